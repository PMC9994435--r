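year,index
2000,172.2
2001,177.1
2002,179.9
2003,184.0
2004,188.9
2005,195.3
2006,201.6
2007,207.342
2008,215.303
2009,214.537
2010,218.056
2011,224.939
2012,229.594
2013,232.957
2014,236.736
2015,237.017
2016,240.007
2017,245.120
2018,251.107
2019,255.657
2020,258.811
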