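patient_id,kind,value,observed_at
P000001,spo2,96,2024-05-02T02:44:16
P000001,spo2,94,2024-05-02T03:44:35
P000004,spo2,96.7,2023-03-10T09:53:31
P000004,spo2,94.9,2023-03-10T10:37:15
P000010,spo2,98.6,2023-07-17T21:30:45
P000012,spo2,89.4,2023-03-21T07:53:07
P000013,spo2,94.6,2023-06-11T01:52:19
P000013,spo2,94.2,2023-06-11T05:28:44
P000013,spo2,94.5,2023-06-11T08:38:38
P000013,spo2,94.5,2023-06-11T10:14:34
P000014,spo2,91.8,2022-08-02T08:05:01
P000014,spo2,94,2022-08-02T23:26:32
P000014,spo2,96,2022-08-03T08:31:21
P000015,spo2,95.4,2024-01-20T04:32:35
P000015,spo2,96.8,2024-01-20T07:45:53
P000015,spo2,95.9,2024-01-20T08:31:26
P000016,spo2,92.2,2024-02-20T05:32:09
P000017,spo2,96,2023-04-24T02:31:21
P000017,spo2,94,2023-04-24T10:44:24
P000019,spo2,97.6,2023-11-02T23:54:23
P000019,spo2,95.8,2023-11-03T00:40:34
P000019,spo2,95.6,2023-11-03T01:48:40
P000020,spo2,90.1,2022-11-15T19:54:46
P000020,spo2,97,2022-11-16T02:21:34
P000020,spo2,94.8,2022-11-16T05:09:11
P000020,spo2,96.7,2022-11-16T11:43:31
P000021,spo2,89.7,2022-02-19T17:38:32
P000022,spo2,96,2024-01-23T21:58:07
P000022,spo2,94,2024-01-24T05:57:37
P000025,spo2,88.9,2022-11-21T06:20:52
P000027,spo2,96.9,2023-12-22T05:13:32
P000027,spo2,98.7,2023-12-22T10:19:17
P000029,spo2,92.8,2023-05-21T13:14:27
P000029,spo2,96,2023-05-23T09:55:25
P000033,spo2,90.9,2023-08-05T02:22:04
P000033,spo2,97.3,2023-08-05T12:14:13
P000034,spo2,97.1,2023-01-05T05:49:01
P000037,spo2,92.5,2022-06-20T12:50:33
P000039,spo2,88.9,2022-12-10T12:54:49
P000039,spo2,94,2022-12-11T03:03:01
P000039,spo2,96,2022-12-11T11:50:10
P000040,spo2,91.9,2024-05-08T21:06:01
P000040,spo2,91.6,2024-05-09T02:10:57
P000040,spo2,90.6,2024-05-09T04:02:53
P000041,spo2,96.2,2022-05-19T13:31:50
P000043,spo2,91.3,2023-06-14T23:02:26
P000043,spo2,97.3,2023-06-15T23:34:04
P000043,spo2,98.9,2023-06-16T02:31:50
P000043,spo2,98.5,2023-06-16T06:43:05
P000043,spo2,100,2023-06-16T07:22:21
P000044,spo2,94,2024-01-14T02:19:51
P000044,spo2,96,2024-01-14T08:18:22
P000046,spo2,92.2,2022-10-11T00:11:01
P000046,spo2,96.2,2022-10-12T01:36:21
P000046,spo2,95.8,2022-10-12T02:14:31
P000046,spo2,96.3,2022-10-12T10:37:56
P000049,spo2,97.8,2023-02-22T01:39:55
P000049,spo2,98.5,2023-02-22T06:03:30
P000049,spo2,99,2023-02-22T06:06:10
P000049,spo2,97.5,2023-02-22T07:49:55
P000050,spo2,93.7,2022-02-03T00:22:50
P000050,spo2,93.2,2022-02-03T04:17:10
P000050,spo2,95.1,2022-02-03T08:00:55
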