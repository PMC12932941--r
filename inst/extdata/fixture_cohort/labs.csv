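patient_id,analyte,value,collected_at
P000001,hemoglobin_serum,6.9,2024-01-25T09:22:00
P000002,hemoglobin_serum,10,2023-10-01T10:48:00
P000002,hemoglobin_serum,13.1,2023-10-06T10:48:00
P000003,hemoglobin_serum,11,2024-03-10T07:24:00
P000005,hemoglobin_serum,8.3,2023-05-20T07:00:00
P000008,hemoglobin_serum,6.9,2023-05-29T17:28:00
P000009,hemoglobin_serum,14.5,2023-12-07T07:21:00
P000010,hemoglobin_serum,12.6,2023-03-24T07:28:00
P000012,hemoglobin_serum,15.5,2023-01-31T09:52:00
P000013,hemoglobin_serum,7.4,2023-06-07T11:43:00
P000014,hemoglobin_serum,10,2022-03-23T10:13:00
P000015,hemoglobin_serum,11.5,2023-10-15T09:20:00
P000016,hemoglobin_serum,11.9,2023-12-18T15:07:00
P000017,hemoglobin_serum,11.8,2022-11-22T11:03:00
P000022,hemoglobin_serum,14.5,2023-12-24T07:23:00
P000027,hemoglobin_serum,11.9,2023-09-01T16:35:00
P000028,hemoglobin_serum,15.1,2022-03-01T09:51:00
P000031,hemoglobin_serum,11.9,2022-11-29T17:18:00
P000031,hemoglobin_serum,10,2023-03-08T17:18:00
P000032,hemoglobin_serum,14.8,2023-07-23T17:05:00
P000035,hemoglobin_serum,9.3,2022-01-31T10:54:00
P000035,hemoglobin_serum,13.8,2022-04-05T10:54:00
P000036,hemoglobin_serum,6,2022-02-15T09:36:00
P000037,hemoglobin_serum,9.3,2021-07-24T07:16:00
P000037,hemoglobin_serum,14,2022-05-25T07:16:00
P000040,hemoglobin_serum,7.6,2024-04-23T08:08:00
P000042,hemoglobin_serum,13.5,2021-11-18T08:05:00
P000044,hemoglobin_serum,8.4,2023-11-02T13:17:00
P000045,hemoglobin_serum,10.9,2023-12-20T10:14:00
P000048,hemoglobin_serum,8.4,2022-02-27T16:18:00
P000048,hemoglobin_serum,13.8,2022-10-16T16:18:00
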