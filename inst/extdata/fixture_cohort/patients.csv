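patient_id,birth_date,sex,pregnant_or_lactating,allergies,preop_copd,preop_supplemental_o2,preop_lung_transplant,preop_recent_uri,preop_sleep_apnea,neuromuscular_disease,gfr_latest,vent_hours_pre_admission,tracheostomy_pre_admission,prior_max_intubation_attempts,exclusion_documented_at
P000001,1957-09-16,female,TRUE,,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,115.8,7.2,FALSE,1,2024-04-02T09:22:00
P000002,1985-09-09,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,68.3,7.5,FALSE,1,
P000003,1982-03-16,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,79.5,24,FALSE,0,
P000004,2008-04-17,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,,18.8,FALSE,0,
P000005,1969-02-10,male,FALSE,sugammadex,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,30,11.4,FALSE,1,2023-10-03T07:00:00
P000006,1957-12-19,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,84.7,24,FALSE,4,
P000007,1987-12-03,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,86,4.7,FALSE,0,
P000008,2001-02-08,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,82.2,7.3,FALSE,1,2023-07-20T17:28:00
P000009,1958-01-14,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,79.4,8.4,FALSE,0,
P000010,1985-05-01,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,,24,FALSE,1,2023-07-19T09:28:00
P000011,1963-08-21,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,30,4.6,FALSE,0,
P000012,1965-03-22,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,76.1,13.9,FALSE,1,
P000013,1936-09-08,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,96.1,24,FALSE,1,
P000014,2000-03-16,female,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,108.6,1.9,FALSE,0,
P000015,1974-10-18,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,89.6,15.6,FALSE,0,
P000016,2004-07-21,female,TRUE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,65,8.2,FALSE,1,2024-02-22T15:53:00
P000017,1960-10-29,female,FALSE,,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,,2.8,FALSE,1,
P000018,1960-03-31,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,96.4,4.4,FALSE,1,
P000019,1986-06-04,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,86.1,24,FALSE,0,
P000020,1939-04-28,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,6.5,24,FALSE,0,2022-10-17T12:34:00
P000021,1981-06-13,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,75.8,11.1,FALSE,1,
P000022,1973-06-22,female,FALSE,,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,63.8,6,FALSE,0,
P000023,1991-03-29,female,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,30,0.9,FALSE,0,
P000024,1986-02-14,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,,13.7,FALSE,0,
P000025,1934-01-24,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,79.9,10.9,FALSE,0,
P000026,1948-01-24,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,118.4,3.6,FALSE,0,
P000027,1990-02-18,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,58.2,15.1,FALSE,1,
P000028,1979-01-22,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,72.2,14.2,FALSE,0,
P000029,1956-05-23,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,75.9,10.4,FALSE,0,
P000030,1957-07-12,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,30,1.5,FALSE,0,
P000031,2002-02-03,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,30,6.9,FALSE,0,
P000032,1987-05-25,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,12.6,17.4,FALSE,0,2023-08-18T19:59:00
P000033,1981-11-30,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,66.6,11,FALSE,0,
P000034,1979-05-04,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,71.1,14.5,FALSE,1,
P000035,1985-05-14,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,78.1,6.3,FALSE,0,
P000036,1934-07-28,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,102.7,17.4,FALSE,1,
P000037,1943-09-14,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,91,2.1,FALSE,0,
P000038,1995-02-28,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,104.9,5.2,FALSE,0,
P000039,1979-09-29,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,71.3,3.7,FALSE,0,
P000040,1972-08-30,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,,4.3,FALSE,0,
P000041,1979-11-02,female,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,60.9,4.7,FALSE,0,
P000042,2006-11-13,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,50.7,4.4,FALSE,0,
P000043,1982-05-06,male,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,,24,FALSE,0,
P000044,1948-10-05,female,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,107.1,6.6,FALSE,0,
P000045,1989-05-22,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,92,6.3,FALSE,1,
P000046,1998-08-03,male,FALSE,penicillin,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,76.6,9.8,FALSE,0,
P000047,1941-04-28,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,98.6,17,FALSE,1,
P000048,1978-12-12,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,49.7,12.2,FALSE,1,
P000049,1947-01-25,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,82,15.2,FALSE,4,
P000050,1952-12-27,female,FALSE,,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,73.5,5.4,FALSE,1,
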