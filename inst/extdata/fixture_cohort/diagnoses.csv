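patient_id,icd10,onset_date
P000001,E11.9,2023-02-20
P000002,K21.9,2019-06-06
P000002,G47.30,2021-04-08
P000003,J47.9,2018-11-17
P000004,K21.9,2019-03-20
P000005,J84.9,2023-05-14
P000006,G47.30,2021-12-07
P000006,E11.9,2022-08-17
P000006,J18.9,2023-08-13
P000011,E11.9,2021-11-27
P000011,G47.9,2023-06-25
P000012,E11.9,2018-06-19
P000013,F41.1,2019-01-27
P000014,G47.39,2018-10-16
P000015,G47.33,2019-07-13
P000015,M54.5,2022-06-23
P000016,G47.39,2021-06-17
P000016,F41.1,2022-06-02
P000017,F41.1,2018-02-03
P000017,J41.9,2023-01-04
P000018,G47.39,2017-12-29
P000018,F41.1,2020-06-10
P000018,J84.8,2021-05-08
P000019,K21.9,2021-06-18
P000019,J84.1,2022-06-03
P000020,I10,2020-08-30
P000020,J00,2022-08-19
P000021,F41.1,2017-07-21
P000021,J06.9,2021-12-17
P000022,K21.9,2023-04-23
P000024,J84.8,2023-07-20
P000025,M54.5,2021-08-30
P000025,J10.1,2022-08-23
P000026,G47.39,2020-12-21
P000026,K21.9,2022-12-11
P000027,K21.9,2019-04-07
P000027,J46,2021-09-12
P000028,J10.1,2022-01-23
P000031,M54.5,2023-02-12
P000031,J15.9,2023-02-27
P000032,G47.30,2018-06-02
P000032,E11.9,2020-06-18
P000032,j20.9,2023-07-17
P000033,M54.5,2020-09-17
P000034,M54.5,2022-04-06
P000035,I10,2022-05-09
P000036,I10,2020-02-10
P000037,I10,2022-04-11
P000037,J06.9,2022-05-26
P000038,M54.5,2019-04-28
P000039,F41.1,2017-10-17
P000040,G47.9,2019-12-20
P000040,I10,2021-09-10
P000042,E11.9,2017-12-03
P000042,G47.33,2019-04-13
P000042,J17,2022-01-07
P000043,J15.9,2023-04-09
P000044,K21.9,2020-07-05
P000045,J84.8,2020-07-26
P000046,D86.0,2018-07-06
P000047,G47.39,2020-01-23
P000047,M54.5,2021-12-17
P000049,J10.1,2023-02-05
P000050,I10,2020-11-11
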