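index	text	correct_key	listening_time_ms
1	Is this school now?	X	1533.5
2	Is the number 9 greater than 6?	O	1948.75
3	Do stones sink in water?	O	1533.25
4	Is a hammer used for cutting wood?	X	1942.75
5	Do you put on your socks before you put on your shoes?	O	2200
6	Is Wednesday the day after Tuesday?	O	1948.5
7	Does it snow in May?	X	1380
8	Is a cat bigger than a mouse?	O	1795.5
9	Are birds eaten by bugs?	X	1792
10	Are banks open on Sunday?	X	1791.25
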