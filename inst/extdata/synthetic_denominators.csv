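birth_year,n
1975,1
1976,1
1977,2
1978,1
1979,1
1980,2
1981,1
1982,1
1983,2
1984,1
1985,1
1986,2
1987,1
1988,1
1989,2
1990,1
1991,1
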