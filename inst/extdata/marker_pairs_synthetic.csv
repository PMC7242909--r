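phase,first,second
G2M,Gene1901,Gene1902
G2M,Gene1903,Gene1904
G2M,Gene1905,Gene1906
G2M,Gene1907,Gene1908
S,Gene1911,Gene1912
S,Gene1913,Gene1914
S,Gene1915,Gene1916
S,Gene1917,Gene1918
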