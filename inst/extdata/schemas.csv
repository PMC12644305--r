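file,column,type,description
cohort.csv,patient_id,integer,unique patient identifier
cohort.csv,exposure,integer 0/1,1 = ICS/LABA-analogue arm; 0 = LABA/LAMA-analogue comparator
cohort.csv,age_group,factor,35-54 / 55-64 / 65-74 / 75+
cohort.csv,gender_female,integer 0/1,female indicator
cohort.csv,bmi_cat,factor,underweight / normal / overweight / obese; may be missing before rule application
cohort.csv,smoking_former,integer 0/1,former (vs current) smoker
cohort.csv,ethnicity,factor,White / South Asian / Black / Mixed (+ Unknown after missing-data rules); may be missing
cohort.csv,imd_quintile,factor,deprivation quintile 1-5; may be missing (rows dropped by rule)
cohort.csv,cancer,integer 0/1,ever diagnosed
cohort.csv,diabetes,integer 0/1,ever diagnosed
cohort.csv,ckd,integer 0/1,chronic kidney disease ever
cohort.csv,cvd,integer 0/1,cardiovascular disease ever
cohort.csv,hypertension,integer 0/1,ever diagnosed
cohort.csv,past_asthma,integer 0/1,asthma more than 3 years ago
cohort.csv,immunosuppression,integer 0/1,immunosuppressed
cohort.csv,flu_vaccine,integer 0/1,influenza vaccination in past year
cohort.csv,pneumo_vaccine,integer 0/1,pneumococcal vaccination in past 5 years
cohort.csv,exacerb_cat,factor,exacerbations in past 12 months: 0 / 1 / 2+
cohort.csv,latent_severity,numeric,latent disease severity (generator verification only; never used in estimation)
cohort.csv,latent_frailty,numeric,latent frailty (generator verification only; never used in estimation)
cohort.csv,triple_therapy,integer 0/1,on triple therapy at index (exposed arm only)
cohort.csv,time_to_event,integer,follow-up in days (1..followup_days)
cohort.csv,event,integer 0/1,outcome indicator
events.csv,patient_id,integer,patient identifier
events.csv,dimension,character,observation / prescription / hospitalisation
events.csv,raw_code,character,raw source-vocabulary code
events.csv,event_date,integer,days before the index date (>= 1)
map_*.csv,source_code,character,raw code (unique within table)
map_*.csv,target_code,character,harmonized code (4-char ICD-like for observations; 6-char paragraph or 8-char chapter for prescriptions)
exclusions.csv,code,character,harmonized codes excluded from the candidate pool
estimates.csv,method,character,conventional or hdps_<k>
estimates.csv,estimand,character,HR / OR / RD
estimates.csv,point;se;lower;upper,numeric,point estimate with robust SE and 95% Wald CI (log scale for ratios)
balance.csv,covariate,character,prespecified covariate or HDPS covariate id (dim:code:level)
balance.csv,SMD_*,numeric,standardized mean difference per weighting scheme
scores.csv,covariate_id;P_C1;P_C0;RR_CE;RR_CD;bias_mult;abs_log_bias;iv_flag;rank,mixed,Bross prioritisation statistics per candidate covariate
unmapped_top100.csv,code;n,mixed,most frequent unmapped raw codes with occurrence counts
diagnostics.csv,k;max_weight;mean_weight;ess_exposed;ess_unexposed;n_trimmed,numeric,stabilized-weight diagnostics per analysis
filter_log.csv,stage;n,mixed,patients/events retained or removed at each filtering stage
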