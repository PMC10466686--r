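person_id,visit_date,report_year,municipality_code,ging_52,ging_55,ging_82,ging_85,ging_12,ging_16,ging_42,ging_46,pato_pocket,surfaces
P000001,1987-09-06,1988,593,0,1,1,0,,,,,,
P000002,1981-09-22,1982,695,0,1,0,0,,,,,,
P000002,1982-08-25,1983,695,0,0,1,2,,,,,,53:B:2;53:D:6;72:L:6;74:L:4;74:O:1;81:O:6;73:L:1
P000002,1983-10-25,1984,695,2,0,0,1,,,,,,85:M:6;54:D:1;71:B:6;71:L:4;62:D:1
P000002,1984-10-14,1985,695,1,0,0,0,,,,,,74:O:6;73:O:2;51:D:2
P000002,1986-08-05,1987,695,0,0,2,1,,,,,,
P000002,1987-08-03,1988,695,,,,,2,0,2,0,,
P000003,1984-11-05,1985,144,2,0,2,0,,,,,,
P000003,1985-12-22,1986,144,1,0,0,1,,,,,,
P000003,1986-11-08,1987,144,0,0,0,1,,,,,,
P000003,1987-10-14,1988,144,1,2,0,0,,,,,,
P000005,1976-01-30,1976,794,0,0,0,0,,,,,,
P000005,1977-02-10,1977,794,1,1,0,1,,,,,,
P000005,1978-02-08,1978,794,1,0,2,1,,,,,,
P000005,1979-03-21,1979,794,0,1,0,0,,,,,,
P000005,1980-03-06,1980,794,2,0,2,0,,,,,,52:O:2;82:D:6;72:B:4;81:B:1;81:M:6;61:B:2
P000005,1981-01-26,1981,794,0,0,1,0,,,,,,85:D:1;84:O:2;81:M:6;55:M:6;81:D:6
P000005,1982-02-20,1982,794,,,,,0,1,2,0,,75:D:4;51:M:1;62:O:1;55:M:1
P000005,1983-03-27,1983,794,,,,,1,1,1,0,,52:L:6;61:L:2;52:D:2;74:D:2;82:B:2;37:B:4
P000005,1983-12-26,1984,794,,,,,0,2,0,0,,62:B:6;55:B:2;38:M:2
P000005,1985-03-11,1985,794,,,,,0,1,1,1,,74:B:6;14:O:2;41:O:4;36:M:1
P000005,1986-03-18,1986,794,,,,,0,1,0,2,,23:D:6;25:M:1;32:M:2
P000005,1986-12-28,1987,794,,,,,1,1,0,2,,61:M:4;33:O:1;23:M:2;16:B:1;44:O:6
P000007,1984-07-23,1984,362,0,0,1,1,,,,,,
P000007,1985-08-31,1986,362,1,1,1,0,,,,,,
P000007,1986-06-07,1986,362,0,1,0,0,,,,,,
P000007,1987-06-12,1987,362,0,0,0,0,,,,,,
P000008,1980-09-09,1981,432,0,2,0,2,,,,,,
P000008,1981-08-08,1982,432,0,1,1,1,,,,,,
P000008,1982-07-07,1982,432,0,1,0,0,,,,,,
P000008,1983-07-21,1983,432,0,1,1,0,,,,,,
P000008,1984-09-10,1985,432,1,2,2,2,,,,,,
P000008,1985-10-07,1986,432,0,0,0,2,,,,,,
P000008,1986-09-21,1987,432,,,,,0,2,1,2,,
P000008,1987-07-01,1987,432,,,,,0,0,0,0,,
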