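asset_name,replacement_cost,useful_life,category
paediatric ward block,1200000,40,building
laboratory analyser,80000,5,lab_equipment
outreach vehicle,30000,5,vehicle
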