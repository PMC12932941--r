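patient_id,observed_at,bmi
P000001,2024-05-02T03:51:15,48.9
P000002,2023-07-09T21:06:02,19.5
P000002,2023-11-03T00:20:29,25.8
P000003,2024-05-03T18:08:15,19.2
P000004,2023-02-09T14:55:47,37.1
P000005,2023-10-19T12:34:22,26.6
P000006,2023-10-19T14:40:20,29
P000007,2024-03-08T21:08:05,36.4
P000008,2022-08-27T23:24:06,33.4
P000008,2023-08-06T00:48:41,35
P000009,2024-02-25T11:01:52,20
P000010,2023-07-15T09:42:13,29.9
P000011,2024-01-30T06:22:55,20.2
P000012,2023-03-22T17:21:17,25.7
P000013,2023-06-01T17:01:07,28.4
P000014,2022-07-18T07:45:02,35
P000015,2023-12-31T15:36:50,30.8
P000016,2023-12-21T05:02:39,29.7
P000016,2024-01-28T03:49:13,20.2
P000017,2023-03-28T06:57:51,20.5
P000018,2023-03-02T08:09:12,51.8
P000019,2023-03-21T00:28:51,40.5
P000019,2023-11-03T00:59:04,33.7
P000020,2022-10-17T14:47:23,22.9
P000021,2021-10-21T05:14:44,29.3
P000021,2022-02-18T04:54:19,26.7
P000022,2024-01-16T10:55:13,35.9
P000023,2023-04-27T02:30:14,19.9
P000024,2023-08-31T14:23:44,40
P000025,2022-11-18T21:08:57,23
P000026,2023-03-02T10:50:36,27.2
P000027,2023-11-29T22:09:32,27.3
P000028,2022-03-18T19:17:44,23.8
P000029,2023-05-14T23:38:31,27.6
P000030,2023-02-06T22:42:32,41.9
P000030,2023-08-02T11:13:38,19.1
P000031,2023-04-15T01:23:09,40
P000032,2023-07-28T23:12:31,40
P000033,2022-09-30T15:03:06,26.5
P000033,2023-07-10T00:11:47,38.8
P000034,2022-12-15T22:43:03,42.1
P000035,2022-08-11T02:47:41,47.7
P000036,2022-04-09T01:18:35,35
P000037,2022-06-02T21:23:48,38.4
P000038,2023-05-01T03:10:07,23.1
P000039,2022-11-14T17:32:17,23.8
P000040,2023-08-02T10:39:25,28
P000040,2024-04-11T22:40:25,22.7
P000041,2022-05-06T09:50:01,30.9
P000042,2021-08-27T22:14:37,42.2
P000042,2022-02-17T10:08:24,33
P000043,2023-06-08T22:27:44,36.7
P000044,2023-11-09T23:39:05,24.7
P000044,2023-12-24T01:16:26,22.1
P000045,2024-05-18T17:14:09,25.2
P000046,2022-10-09T00:50:20,51.1
P000047,2022-02-06T22:51:53,30.9
P000048,2023-01-24T03:29:54,25.5
P000049,2022-03-02T06:12:00,19.4
P000049,2023-02-16T10:35:25,53.9
P000050,2022-01-29T08:58:15,30.4
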