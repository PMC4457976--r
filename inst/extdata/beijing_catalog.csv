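service_id,name,category,delivery_unit,in_nephsp,workload_urban,workload_suburban
clinic_visit,Clinic visit,basic_medical,per visit,FALSE,15.00,15.00
emergency,Emergency,basic_medical,per visit,FALSE,40.35,52.50
home_visit,Home visit,basic_medical,per visit,FALSE,60.00,60.00
inpatient_bed_day,Inpatient bed day,basic_medical,per bed day,FALSE,100.05,180.00
rehab_clinic,Rehabilitation clinic,basic_medical,per outpatient visit,FALSE,30.00,30.00
iv_injection,Intravenous injection,nursing,per procedure,FALSE,7.50,6.00
iv_infusion,Intravenous infusion,nursing,per procedure,FALSE,12.00,11.70
venous_blood_draw,"Intravenous injection, venous blood",nursing,per procedure,FALSE,9.30,9.45
catheterization,Catheterization,nursing,per procedure,FALSE,28.95,19.50
prescription_western,Providing prescription (western medicine),nursing,per prescription,FALSE,4.50,6.00
dispensing,Providing medication to meet a prescription,pharmacy,per prescription,FALSE,19.95,19.95
advanced_pharmacy,Advanced pharmacy work with detailed dosage calculations,pharmacy,per prescription,FALSE,63.60,60.00
rapid_blood_sugar,Rapid blood sugar test,auxiliary_exam,per test,FALSE,4.50,4.65
blood_urine_feces_test,"Blood, urine, feces test",auxiliary_exam,per test,FALSE,9.00,9.15
biochemical_test,Biochemical test,auxiliary_exam,per test,FALSE,30.00,27.45
ecg,Electrocardiogram,auxiliary_exam,per test,FALSE,11.25,10.05
ultrasound_b,B-mode ultrasonography,auxiliary_exam,per test,FALSE,19.95,19.95
health_records,Health records management service,nephsp,per person year,TRUE,1019.25,972.00
health_education,Health education service,nephsp,per center,TRUE,47076.00,34650.00
child_health,Health services for children aged 0 to 36 months,nephsp,per person year,TRUE,173.40,203.40
maternal_health,Maternal health services,nephsp,per person year,TRUE,210.00,262.50
older_people_health,Older people's health services,nephsp,per person year,TRUE,60.00,49.95
immunization,Immunizations,nephsp,per visit,TRUE,25.05,15.45
infectious_disease,Infectious disease reporting and treatment,nephsp,per time,TRUE,5913.63,4979.40
hypertension_mgmt,Health services for patients with hypertension,nephsp,per person year,TRUE,190.05,152.55
diabetes_mgmt,Services for patients with type II diabetes,nephsp,per person year,TRUE,190.05,147.45
mental_illness_mgmt,Services for patients with severe mental illness,nephsp,per person year,TRUE,472.50,420.00
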