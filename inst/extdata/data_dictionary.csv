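column,type,values,description
id,integer,1..n,Respondent identifier
country,character,"IT, ES, UK",Country of residence
gender,character,"F, M",Gender
age,integer,18-75,Age in years
region,character,see region_codes(),Macro-region of residence (4 for IT; 5 for ES and UK)
arm,character,"control, T1, T2, direct",Randomized list-experiment arm
item_count,integer,0-4 (control) / 0-5 (T1/T2); NA in direct arm,Number of shown statements agreed with
direct_ctrl1,integer,"0/1; NA outside direct arm",Agreement with control statement 1 (direct arm)
direct_ctrl2,integer,"0/1; NA outside direct arm",Agreement with control statement 2 (direct arm)
direct_ctrl3,integer,"0/1; NA outside direct arm",Agreement with control statement 3 (direct arm)
direct_ctrl4,integer,"0/1; NA outside direct arm",Agreement with control statement 4 (direct arm)
direct_sens1,integer,"0/1; NA outside direct arm",Reported agreement with sensitive statement 1 (after lying mechanism)
direct_sens2,integer,"0/1; NA outside direct arm",Reported agreement with sensitive statement 2 (after lying mechanism)
income_category,integer,1-10 (ordinal),Household income category
unemployed,integer,0/1,In search of a job
married,integer,0/1,Married or cohabiting
homeowner,integer,0/1,Dwelling owned and fully paid
living_area,numeric,>= 20,Useful living area in square metres
household_size,integer,1-7,People in the household
children_school,integer,0-3,Children of school age in the household
education,integer,1-5 (ordinal),Educational attainment
buffer_stock,integer,1-5 (ordinal),Financial buffer: how long bills can be covered after losing the job
stress_events,integer,0-8,Count of negative events in the previous week
income_loss,integer,0/1,Wage or earnings negatively affected by the outbreak
mh1..mh8,integer,1-4,Stress/anxiety/depression items (frequency over the previous week)
comorb_diabetes,integer,0/1,Diagnosed diabetes
comorb_hypertension,integer,0/1,Diagnosed hypertension
comorb_asthma,integer,0/1,Diagnosed asthma
comorb_cardio,integer,0/1,Diagnosed cardiovascular disease
comorb_cancer,integer,0/1,Diagnosed cancer
health_selfrated,integer,1-5 (ordinal; high = poor),Self-rated health
vuln1..vuln4,integer,1-4 (ordinal),Obstacles preventing full quarantine compliance
contacted_doctor,integer,0/1,Contacted a doctor because of COVID-19
contacted_authorities,integer,0/1,Contacted health authorities because of COVID-19
sought_test,integer,0/1,Sought to get tested for COVID-19
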