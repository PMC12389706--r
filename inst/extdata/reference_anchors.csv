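# Independent reference values with relative tolerances
quantity,material,energy_keV,value,tolerance,provenance
mu_total,water,50,0.2269,0.02,published water mass attenuation table
mu_total,water,100,0.1707,0.02,published water mass attenuation table
mu_total,water,500,0.09687,0.02,published water mass attenuation table
mu_total,water,1000,0.07072,0.02,published water mass attenuation table
collision_stopping,water,100,4.115,0.06,published electron stopping-power table
collision_stopping,water,1000,1.849,0.05,published electron stopping-power table
csda_range,water,300,0.0844,0.1,published electron CSDA range table
csda_range,water,1000,0.4367,0.1,published electron CSDA range table
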