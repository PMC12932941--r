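case_id,drug,source,administered_at,ordered_via_bpa
C000002,rocuronium,na,2023-11-09T11:03:00,FALSE
C000002,neostigmine,standard_stock,2023-11-09T12:23:12,FALSE
C000003,rocuronium,na,2024-05-09T07:39:00,FALSE
C000003,sugammadex,study_pathway,2024-05-09T10:29:36,TRUE
C000004,rocuronium,na,2023-03-10T13:48:00,FALSE
C000006,rocuronium,na,2023-11-06T12:09:00,FALSE
C000006,sugammadex,standard_stock,2023-11-06T15:42:00,FALSE
C000007,rocuronium,na,2024-04-02T07:32:00,FALSE
C000009,rocuronium,na,2024-02-27T07:36:00,FALSE
C000009,sugammadex,standard_stock,2024-02-27T08:53:48,FALSE
C000010,rocuronium,na,2023-07-18T07:43:00,FALSE
C000010,neostigmine,standard_stock,2023-07-18T09:04:00,FALSE
C000011,rocuronium,na,2024-02-26T08:23:00,FALSE
C000012,rocuronium,na,2023-03-23T10:07:00,FALSE
C000012,neostigmine,standard_stock,2023-03-23T11:28:00,FALSE
C000014,rocuronium,na,2022-08-03T10:28:00,FALSE
C000014,sugammadex,standard_stock,2022-08-03T11:45:00,FALSE
C000015,sugammadex,standard_stock,2024-01-20T10:14:24,FALSE
C000016,rocuronium,na,2024-02-21T15:22:00,FALSE
C000016,neostigmine,standard_stock,2024-02-21T15:43:48,FALSE
C000017,sugammadex,study_pathway,2023-04-24T12:39:00,TRUE
C000018,rocuronium,na,2023-03-25T09:44:00,FALSE
C000019,sugammadex,standard_stock,2023-11-03T11:23:12,FALSE
C000020,rocuronium,na,2022-11-16T12:49:00,FALSE
C000020,neostigmine,standard_stock,2022-11-16T14:18:00,FALSE
C000021,rocuronium,na,2022-02-20T10:09:00,FALSE
C000022,rocuronium,na,2024-01-24T07:38:00,FALSE
C000022,sugammadex,standard_stock,2024-01-24T07:57:24,FALSE
C000024,rocuronium,na,2023-09-21T11:51:00,FALSE
C000024,sugammadex,study_pathway,2023-09-21T16:04:00,TRUE
C000025,rocuronium,na,2022-11-21T15:12:00,FALSE
C000025,neostigmine,standard_stock,2022-11-21T15:37:00,FALSE
C000026,rocuronium,na,2023-03-18T10:45:00,FALSE
C000026,neostigmine,standard_stock,2023-03-18T15:27:36,FALSE
C000027,rocuronium,na,2023-12-22T16:50:00,FALSE
C000027,sugammadex,standard_stock,2023-12-22T17:01:24,FALSE
C000028,rocuronium,na,2022-04-07T10:06:00,FALSE
C000030,rocuronium,na,2023-08-06T10:10:00,FALSE
C000030,neostigmine,standard_stock,2023-08-06T16:08:36,FALSE
C000031,sugammadex,standard_stock,2023-05-05T17:42:48,FALSE
C000032,sugammadex,study_pathway,2023-08-17T19:24:12,TRUE
C000033,rocuronium,na,2023-08-05T17:08:00,FALSE
C000033,sugammadex,standard_stock,2023-08-05T20:02:36,FALSE
C000034,sugammadex,study_pathway,2023-01-05T17:00:48,TRUE
C000035,rocuronium,na,2022-08-11T11:09:00,FALSE
C000035,sugammadex,standard_stock,2022-08-11T11:27:36,FALSE
C000036,rocuronium,na,2022-04-19T09:51:00,FALSE
C000036,sugammadex,standard_stock,2022-04-19T10:10:24,FALSE
C000037,rocuronium,na,2022-06-22T07:31:00,FALSE
C000037,sugammadex,study_pathway,2022-06-22T12:32:48,TRUE
C000039,rocuronium,na,2022-12-11T12:49:00,FALSE
C000039,neostigmine,standard_stock,2022-12-11T13:26:48,FALSE
C000040,rocuronium,na,2024-05-09T08:23:00,FALSE
C000040,neostigmine,standard_stock,2024-05-09T09:41:36,FALSE
C000041,rocuronium,na,2022-05-19T15:27:00,FALSE
C000043,rocuronium,na,2023-06-16T08:10:00,FALSE
C000043,sugammadex,standard_stock,2023-06-16T14:15:48,FALSE
C000044,rocuronium,na,2024-01-14T13:32:00,FALSE
C000044,sugammadex,study_pathway,2024-01-14T19:11:24,TRUE
C000045,rocuronium,na,2024-05-27T10:29:00,FALSE
C000045,neostigmine,standard_stock,2024-05-27T15:32:24,FALSE
C000046,sugammadex,standard_stock,2022-10-12T13:45:36,FALSE
C000047,rocuronium,na,2022-02-26T09:55:00,FALSE
C000048,rocuronium,na,2023-02-11T16:33:00,FALSE
C000048,neostigmine,standard_stock,2023-02-11T17:54:00,FALSE
C000049,rocuronium,na,2023-02-22T13:32:00,FALSE
C000049,sugammadex,study_pathway,2023-02-22T14:01:00,TRUE
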