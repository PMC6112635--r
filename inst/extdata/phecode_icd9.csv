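icd9,phecode
250.00,250.2
250.02,250.2
250.01,250.1
250.03,250.1
250.40,250.21
250.42,250.21
250.41,250.11
250.43,250.11
250.50,250.22
250.52,250.22
250.51,250.12
250.53,250.12
250.60,250.23
250.62,250.23
250.61,250.13
250.63,250.13
250.70,250.24
250.72,250.24
250.71,250.14
250.73,250.14
250.80,250.25
250.82,250.25
250.90,250.25
250.92,250.25
250.81,250.15
250.83,250.15
250.91,250.15
250.93,250.15
410.00,411.2
410.90,411.2
410.91,411.2
411.1,411.8
411.81,411.8
411.89,411.8
413.9,411.3
414.00,411.4
585.4,585.34
585.5,585.32
585.6,585.31
401.1,401.1
401.9,401.1
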