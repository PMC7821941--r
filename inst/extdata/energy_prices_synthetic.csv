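# Synthetic approximation of US national-average industrial energy prices,
# 1999-2019, expressed in January-2019 dollars (inflation-adjusted).
# electricity_usd_per_kwh: industrial retail electricity price
# gas_usd_per_kcf: industrial natural gas price per 1000 cubic feet
# Values are package-constructed estimates for fitting the linear
# electricity-vs-gas price relation; they are not a published data table.
year,electricity_usd_per_kwh,gas_usd_per_kcf
1999,0.0668,4.70
2000,0.0683,6.54
2001,0.0715,7.22
2002,0.0688,5.38
2003,0.0708,7.85
2004,0.0702,8.45
2005,0.0741,10.70
2006,0.0776,9.55
2007,0.0782,9.58
2008,0.0818,11.16
2009,0.0809,6.18
2010,0.0795,6.27
2011,0.0767,5.66
2012,0.0742,4.21
2013,0.0745,4.98
2014,0.0756,5.81
2015,0.0731,4.20
2016,0.0722,3.70
2017,0.0716,4.32
2018,0.0702,4.35
2019,0.0681,3.90
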