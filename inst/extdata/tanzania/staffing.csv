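cadre,level,scenario,count,monthly_salary_usd
nurse,district,A,13,420
clinical_officer,district,A,4,380
medical_doctor,district,A,4,850
nursing_assistant,district,A,3,220
ward_clerk,district,A,2,260
biomedical_technician,district,A,1,480
nurse,regional,A,20,420
clinical_officer,regional,A,0,380
medical_doctor,regional,A,12,850
nursing_assistant,regional,A,9,220
ward_clerk,regional,A,2,260
biomedical_technician,regional,A,1,480
nurse,district,B,7,420
clinical_officer,district,B,2,380
medical_doctor,district,B,2,850
nursing_assistant,district,B,1,220
ward_clerk,district,B,0,260
biomedical_technician,district,B,0,480
nurse,regional,B,10,420
clinical_officer,regional,B,0,380
medical_doctor,regional,B,6,850
nursing_assistant,regional,B,5,220
ward_clerk,regional,B,1,260
biomedical_technician,regional,B,0,480
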