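name,classification,halys_gained,intervention_cost_m,first3y_cost_m,cost_offsets_m,net_cost_m,icer,evidence_bmi
Alcohol price increase: uniform volumetric tax,regulatory,471165,32,25,4800,-4800,,low
Sugar-sweetened beverages tax - 20%,regulatory,175300,120,12,1700,-1600,,low
Restricting television advertising of unhealthy foods,regulatory,88396,6,1.5,784,-778,,low
Package size cap on sugar-sweetened beverages,regulatory,73883,210,144,751,-541,,low
Supermarket shelf tags on healthier products,program,72532,9,9,647,-638,,low
Menu kilojoule labelling on fast food,regulatory,63492,170,37,672,-502,,low
School-based intervention to reduce sedentary behaviour,program,61989,15,14,661,-646,,medium
School-based intervention to increase physical activity,program,60780,10,10,641,-631,,medium
Restrictions on price promotions of sugar-sweetened beverages,regulatory,48336,17,5,498,-481,,low
Reformulation to reduce sugar in sugar-sweetened beverages,regulatory,28981,45,31,295,-251,,low
National mass media campaign related to sugar-sweetened beverages,program,13958,31,31,157,-127,,low
Reformulation in response to the Health Star Rating system,regulatory,4207,46,31,42,5,1728,low
Financial incentives for weight loss provided by private health insurers,program,140110,1700,1600,692,1000,7376,high
Fuel excise: 10c per litre increase,regulatory,237,4.4,4,2,2,7684,low
Community-based interventions,program,51792,878,878,452,426,8155,high
Workplace intervention to reduce sedentary behaviour,program,7492,269,269,54,215,28703,low
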