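year,capture_C,capture_R,biopsy_C,biopsy_R
2001,63,0,0,0
2002,78,8,0,0
2003,92,9,0,0
2004,124,22,0,0
2005,80,22,0,0
2006,85,31,0,0
2007,76,22,0,0
2008,78,25,0,0
2009,92,36,0,0
2010,65,29,0,0
2011,61,20,39,18
2012,74,30,24,12
2013,56,20,30,13
2014,48,20,0,0
2015,38,12,0,0
2016,21,7,0,0
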