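person_id,visit_date,report_year,municipality_code,ging_11,ging_12,ging_21,ging_22,ging_31,ging_32,ging_41,ging_42,ging_16,ging_26,ging_36,ging_46,poch_11,poch_12,poch_21,poch_22,poch_31,poch_32,poch_41,poch_42,poch_16,poch_26,poch_36,poch_46,surfaces
P000001,1988-08-18,1988,593,,,,,,,,,,,,,,,,,,,,,,,,,
P000001,1990-07-31,1990,593,,,,,,2,,,,,,,,,,,,,,,,,,,
P000001,1992-08-28,1992,593,,,,,,,,,,,,,,,5,,,,,,,,,,
P000001,1993-10-04,1993,593,,,,,,,,,,,,,,,,,,,,,,,,,82:B:4;72:L:4;84:M:1
P000001,1995-07-22,1995,593,2,2,2,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,
P000001,1996-08-17,1996,593,,2,,,,,,,,,,,,,,,5,5,,,,,,,
P000001,1997-09-26,1997,593,,,,,,,,,,,,,,,,,,,,,,,,,
P000001,1999-10-11,1999,593,,,2,,,,,,,,,,,,,,,,,,,,,,
P000002,1988-10-22,1988,695,,,,,,,,,,,,,,,,,,,,,,,,,
P000002,1989-07-31,1989,695,,,,,,,,,,,,,5,5,5,5,5,5,5,5,5,5,,5,
P000002,1990-10-26,1990,695,,,,,,,,,,,,,5,5,5,5,5,5,5,5,5,5,5,5,
P000002,1991-10-05,1991,695,,,,,,,,,,,,2,5,5,5,5,5,5,5,5,5,5,,,
P000002,1992-08-13,1992,695,,,,,,,,,,,,,5,5,5,5,5,5,5,5,5,5,5,5,
P000002,1993-11-04,1993,695,,,,,,,,,,,,,,,,,,,,,,,,,
P000002,1996-08-26,1996,695,,,,2,2,,,,,,,,,,,,,,,,,,,,
P000002,1998-08-03,1998,695,2,2,2,2,2,,,,,,,,,,,,,,,,,,,,13:B:4;28:D:4;26:L:1;38:O:1;46:M:6;41:O:6;48:O:2
P000002,1999-07-25,1999,695,,,,,,,,,,,,,,,,,,,,,,,,,33:M:2;43:O:6;11:D:2;17:M:2;27:D:1
P000003,1989-01-25,1989,144,,,,,,,2,2,2,2,2,,,,,,,,,,,,,,
P000003,1989-10-09,1989,144,,,,,,,,,,,,,,,,,,,,,,,,,
P000003,1991-01-16,1991,144,,,,,,,,2,,,,,,,,,,,,,,,,,
P000003,1992-02-02,1992,144,2,2,2,,,,,,,,,,,,,,,,,,,,,,
P000003,1994-11-29,1994,144,,2,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,,
P000003,1996-12-25,1996,144,2,2,2,2,,,,,2,2,2,2,,,,,,,,,,,,,
P000003,1997-12-27,1997,144,,,2,2,2,2,2,2,,,,,,,,,,,,,,,,5,
P000003,1999-12-03,1999,144,2,2,2,2,,,,,,2,2,2,,,,,,,,,,,,,
P000004,1989-10-27,1989,381,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1990-11-24,1990,381,,,,,,,,,,2,2,2,,,,,,,,,,,,,65:M:2;62:B:4;83:O:2;74:L:6;63:M:2;84:B:1
P000004,1992-01-23,1992,381,,,,,,,,,2,2,2,,,,,,,,,,,,,,
P000004,1992-10-26,1992,381,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1994-01-22,1994,381,2,,,,,,,,,,2,2,,,,,,,,,,,5,,
P000004,1995-01-04,1995,381,,,,2,2,2,2,2,,,,,,,,,,,,,,,,,
P000004,1995-11-03,1995,381,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1996-11-12,1996,381,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1997-11-22,1997,381,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1998-10-24,1998,381,,,,,2,2,2,2,,,,,,,,,,,,,,,,,
P000005,1989-03-21,1989,794,,,2,,,,,,,,,,,,,,,,,,,,,,33:O:6;16:M:2;12:D:4
P000005,1991-02-28,1991,794,,,,,,,,,,,,,,,,,,,,,,,,,
P000005,1992-03-04,1992,794,,,,,,,2,2,2,2,,,,,,,,,,,,,,,
P000006,1991-04-01,1991,773,2,2,2,2,2,2,2,2,2,2,2,2,,5,,,,,,,,,,,
P000006,1993-03-24,1993,773,2,2,2,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,81:M:1;51:O:2;54:D:4;85:M:1
P000006,1994-02-26,1994,773,,2,2,2,2,2,2,2,2,,,,,,,,,,,,,,,,
P000006,1995-03-07,1995,773,2,2,2,2,2,,,,,,2,2,,,,,,,,,,,,,83:B:1;52:M:4;64:D:4;75:O:4;53:L:6
P000006,1996-03-09,1996,773,2,2,2,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,
P000006,1997-06-13,1997,773,2,2,2,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,
P000006,1998-06-05,1998,773,2,2,2,2,2,,,,,,,2,,,,,,,,,,,,,
P000006,1999-06-01,1999,773,2,2,2,2,2,,,,,,2,2,,,,,,,,,,,,,
P000007,1988-07-26,1988,362,,,,,,,,,,,,,,,,,,,,,,,,,
P000007,1989-08-26,1989,362,,,,,,,,,,,,,,,,,,,,,,,,,
P000007,1990-09-02,1990,362,,,,,,,,,,,,,,,,,,,5,,,,,,
P000007,1991-07-18,1991,362,2,2,,,,,2,2,2,2,2,2,,,,,,,,,,,5,,
P000007,1992-05-24,1992,362,2,2,2,2,2,2,2,2,2,,2,2,,,,,,,,,,,,,
P000007,1993-06-04,1993,362,,2,2,2,2,2,2,2,2,,,,,,,,,,,,,,,,
P000007,1994-05-23,1994,362,,,2,2,2,2,2,2,2,,,,,,,,,,,,,,,5,
P000007,1996-08-06,1996,362,,2,2,2,2,2,2,2,2,2,,,,,,,,,,,,,,,74:O:1;36:L:6;41:O:6;15:B:2;14:B:6;25:O:6
P000007,1999-05-10,1999,362,,,,,,,,,,,,,,,,,,,,,,,,,
P000008,1988-09-26,1988,432,,,,,,,,,,,,,,,,,5,,,,,,,,
P000008,1989-08-01,1989,432,,,,,,,,,,,,,,,,,,,,,,,,,64:M:6;82:D:2;53:M:1;63:D:4
P000008,1990-08-07,1990,432,,,2,2,2,2,,,,,,,,,,,,,,,,,,,83:O:1;81:M:4;18:M:6;31:O:1;16:M:2;27:M:2
P000008,1991-10-13,1991,432,,,,,,,2,2,,,,,,5,,,,,,,,,,,
P000008,1992-06-27,1992,432,,,,,,,2,2,,,,,,,,,,,,,,,,,
P000008,1995-07-27,1995,432,,,,,,,,,,,,,,,,,,,,,,,,,
P000008,1997-08-29,1997,432,,2,,,,,,,,,,,,,,,,,,,,,,,
P000008,1998-09-30,1998,432,,,,,,,,,,,,,,,,,,,,,,,,,
P000004,1990-11-24,1990,381,,,,,,,,,,2,2,2,,,,,,,,,,,,,65:M:2;62:B:4;83:O:2;74:L:6;63:M:2;84:B:1
P000004,1995-01-04,1995,381,,,,2,2,2,2,2,,,,,,,,,,,,,,,,,
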