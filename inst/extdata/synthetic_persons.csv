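person_id,sex,birth_date,death_date
P000001,M,1987-06-07,
P000002,F,1981-07-03,
P000003,M,1984-09-16,
P000004,F,1989-10-04,2007-11-13
P000005,M,1975-12-04,
P000006,F,1991-01-16,2009-04-18
P000007,M,1984-04-04,2002-08-22
P000008,M,1980-05-26,
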