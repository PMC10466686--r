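person_id,visit_date,report_year,municipality_code,ging_11,ging_12,ging_21,ging_22,ging_31,ging_32,ging_41,ging_42,ging_16,ging_26,ging_36,ging_46,poch_11,poch_12,poch_21,poch_22,poch_31,poch_32,poch_41,poch_42,poch_16,poch_26,poch_36,poch_46,surfaces
P000001,2000-08-11,,593,,1,,,,,,,,,,,0,0,0,0,0,0,0,0,0,0,0,0,12:D:6;43:M:2;27:M:6;16:L:4;14:L:1
P000001,2001-10-09,,593,,,,,,,1,1,1,1,,,0,0,0,0,0,0,0,0,0,0,0,0,16:M:2;32:L:4;17:M:4;24:O:6;22:M:6;16:O:2
P000001,2003-07-01,,593,1,,,,,,,,,1,1,1,1,1,1,1,1,1,1,1,0,1,1,1,12:B:4;38:B:4;32:B:6;42:B:4;17:M:1;32:M:2;17:B:2
P000001,2004-07-03,,593,,,1,,,,,,,,,,0,0,1,1,0,0,0,0,0,0,0,0,24:M:4;47:D:1;45:D:4
P000003,2001-01-07,,144,1,1,1,1,1,1,1,,,,1,1,0,0,0,0,0,0,0,0,0,0,0,0,
P000003,2002-11-16,,144,,1,1,1,1,1,1,1,1,1,1,,0,0,0,0,0,0,0,0,0,0,0,0,
P000004,2001-02-21,,381,,,,,,,,,,,1,1,0,0,0,0,0,0,0,0,0,0,0,0,71:M:2;31:B:6;17:D:4;24:O:2
P000004,2002-01-06,,381,,,,,,,,,,,,,0,0,0,0,0,0,0,0,0,0,0,0,
P000004,2005-02-10,,381,,,,,,,,,,,,,0,0,0,0,0,0,0,0,0,0,0,0,
P000004,2007-02-02,,381,,,,,,,,,,,,,0,0,0,0,0,0,0,0,0,0,0,0,
P000004,2007-11-14,,381,,,,,,,,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,
P000006,2000-04-01,,773,,,,,,,,,,,,,0,0,0,0,0,0,0,0,0,0,1,1,
P000006,2002-05-31,,773,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,64:M:1;82:B:1;33:O:1;27:B:4;16:D:2;47:M:1;33:M:2;26:L:2
P000006,2003-03-24,,773,,,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,28:D:2;38:B:1
P000006,2004-04-08,,773,1,1,1,,,,,,1,1,1,1,0,1,1,1,1,1,1,1,1,1,0,0,22:D:1;21:B:6;47:B:1;47:D:1;26:M:6
P000006,2005-06-03,,773,1,1,1,1,,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,1,1,1,11:O:1;43:O:6;35:O:2
P000006,2006-05-11,,773,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0,0,1,1,1,1,28:O:6;34:B:2;18:L:1
P000006,2009-04-19,,773,,,1,1,,,,,,,,,0,0,0,0,0,0,0,0,0,0,0,0,11:L:2;47:L:6;11:O:4;42:M:2;45:D:1;22:B:2;24:O:1
P000007,2000-07-07,,362,,,1,1,1,1,1,1,,,,,0,0,0,0,0,0,0,0,0,0,0,0,15:L:6;45:B:2;32:M:6;32:O:4;46:O:2;45:O:6
P000007,2001-05-22,,362,1,1,1,1,1,1,1,1,,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,26:B:2;34:D:1;23:D:6;32:O:4
P000007,2002-08-23,,362,1,1,1,,,,,,,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,18:M:2;23:O:6;28:O:1;46:D:2;27:B:2;38:D:4
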