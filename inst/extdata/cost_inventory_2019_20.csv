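modality,category,description,amount,lifespan_years,monthly_salary,apportioning_statistic
P-AABR,human_resource,Staff nurse,NA,NA,15000,1
P-AABR,human_resource,Data entry operator/technician,NA,NA,18000,1
P-AABR,human_resource,Post-service training per person,25000,NA,NA,NA
P-AABR,medical_consumables,Electrodes and sedatives,104520,NA,NA,NA
P-AABR,medical_equipment,Portable automated ABR device,448416,6,NA,NA
P-AABR,overheads,Electricity and water per annum,2400,NA,NA,NA
OAE,human_resource,Staff nurse,NA,NA,15000,1
OAE,human_resource,Data entry operator/technician,NA,NA,18000,1
OAE,human_resource,Post-service training per person,25000,NA,NA,NA
OAE,medical_consumables,Probes and consumables,140400,NA,NA,NA
OAE,medical_equipment,OAE screening device,353298,6,NA,NA
OAE,overheads,Electricity and water per annum,2400,NA,NA,NA
BERA,human_resource,Audiologist,NA,NA,50000,1
BERA,human_resource,Staff nurse,NA,NA,15000,1
BERA,human_resource,Data entry operator/technician,NA,NA,18000,1
BERA,human_resource,Pediatrician/Anesthesiologist,NA,NA,90000,0.25
BERA,human_resource,Post-service training per person,25000,NA,NA,NA
BERA,medical_consumables,Electrodes and sedatives,174720,NA,NA,NA
BERA,non_medical_consumables,Stationery and cartridge,4000,NA,NA,NA
BERA,medical_equipment,BERA system,1122642,6,NA,NA
BERA,non_medical_equipment,Building/space (annualized),139354,NA,NA,NA
BERA,overheads,Electricity and water per annum,30000,NA,NA,NA
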