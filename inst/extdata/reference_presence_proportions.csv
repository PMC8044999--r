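structure,tracer,group,n,proportion
nasal_turbinates,fluorescein_500k,10min,3,0.67
nasal_turbinates,fluorescein_500k,10+80min,7,1.00
nasal_turbinates,texas_red_3k,10min,3,0.33
nasal_turbinates,texas_red_3k,10+80min,7,1.00
olfactory_bulb,fluorescein_500k,10min,3,0.00
olfactory_bulb,fluorescein_500k,10+80min,7,0.57
olfactory_bulb,texas_red_3k,10min,3,0.00
olfactory_bulb,texas_red_3k,10+80min,7,0.14
cortex,fluorescein_500k,10min,3,0.33
cortex,fluorescein_500k,10+80min,7,0.43
cortex,texas_red_3k,10min,3,0.67
cortex,texas_red_3k,10+80min,7,0.86
hippocampus,fluorescein_500k,10min,3,1.00
hippocampus,fluorescein_500k,10+80min,7,1.00
hippocampus,texas_red_3k,10min,3,1.00
hippocampus,texas_red_3k,10+80min,7,1.00
striatum,fluorescein_500k,10min,3,0.00
striatum,fluorescein_500k,10+80min,7,0.00
striatum,texas_red_3k,10min,3,0.67
striatum,texas_red_3k,10+80min,7,0.86
sas_cerebrum,fluorescein_500k,10min,3,0.33
sas_cerebrum,fluorescein_500k,10+80min,7,0.57
sas_cerebrum,texas_red_3k,10min,3,0.33
sas_cerebrum,texas_red_3k,10+80min,7,0.86
lateral_ventricle,fluorescein_500k,10min,3,1.00
lateral_ventricle,fluorescein_500k,10+80min,7,0.86
lateral_ventricle,texas_red_3k,10min,3,1.00
lateral_ventricle,texas_red_3k,10+80min,7,1.00
third_ventricle,fluorescein_500k,10min,3,0.67
third_ventricle,fluorescein_500k,10+80min,7,0.86
third_ventricle,texas_red_3k,10min,3,1.00
third_ventricle,texas_red_3k,10+80min,7,1.00
fourth_ventricle,fluorescein_500k,10min,3,0.33
fourth_ventricle,fluorescein_500k,10+80min,7,0.71
fourth_ventricle,texas_red_3k,10min,3,0.14
fourth_ventricle,texas_red_3k,10+80min,7,0.86
interpeduncular_cistern,fluorescein_500k,10min,3,1.00
interpeduncular_cistern,fluorescein_500k,10+80min,7,0.71
interpeduncular_cistern,texas_red_3k,10min,3,1.00
interpeduncular_cistern,texas_red_3k,10+80min,7,0.86
sas_cerebellum,fluorescein_500k,10min,3,0.33
sas_cerebellum,fluorescein_500k,10+80min,7,0.71
sas_cerebellum,texas_red_3k,10min,3,0.67
sas_cerebellum,texas_red_3k,10+80min,7,1.00
spinal_cord,fluorescein_500k,10min,3,0.33
spinal_cord,fluorescein_500k,10+80min,7,0.86
spinal_cord,texas_red_3k,10min,3,0.33
spinal_cord,texas_red_3k,10+80min,7,1.00
spinal_nerves,fluorescein_500k,10min,3,0.00
spinal_nerves,fluorescein_500k,10+80min,7,0.86
spinal_nerves,texas_red_3k,10min,3,0.33
spinal_nerves,texas_red_3k,10+80min,7,1.00
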