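sample_id,origin,n_mtdna,A,C,D,E,F,K,I,J,M,N,P,O,Q,S,T
1987,wild,37,0.459,0.162,0.162,0.054,0.081,0.027,0,0,0.054,0,0,0,0,0,0
1999,wild,44,0.750,0,0.114,0.068,0.045,0.023,0,0,0,0,0,0,0,0,0
2000,wild,124,0.790,0.008,0.048,0.048,0.097,0.008,0,0,0,0,0,0,0,0,0
2001,wild,122,0.607,0.090,0.057,0.033,0.098,0.074,0.008,0.016,0.008,0,0,0.008,0,0,0
2002,wild,387,0.556,0.199,0.137,0.010,0.059,0.034,0,0.003,0,0,0,0.003,0,0,0
2003,wild,167,0.671,0.054,0.150,0.030,0.054,0.012,0,0.006,0.006,0,0,0.018,0,0,0
2004,wild,161,0.596,0.087,0.106,0.019,0.075,0.050,0.012,0,0.019,0,0.006,0.031,0,0,0
2005,wild,396,0.598,0.126,0.088,0.028,0.086,0.018,0.015,0.003,0.028,0,0,0.010,0,0,0
2006,wild,378,0.587,0.135,0.093,0.048,0.048,0.048,0.003,0,0.029,0,0,0.008,0,0,0.003
2007,wild,218,0.628,0.110,0.083,0.023,0.087,0.037,0.005,0,0.005,0,0,0.018,0.005,0,0
2008,wild,466,0.635,0.120,0.079,0.026,0.067,0.045,0.004,0,0.009,0,0.002,0.006,0,0.006,0
2009,wild,472,0.614,0.140,0.076,0.028,0.064,0.034,0.006,0.004,0.019,0,0.002,0.011,0,0.002,0
2010,wild,433,0.562,0.124,0.097,0.032,0.069,0.053,0.014,0,0.016,0,0,0.032,0,0,0
WcE-01,wild_caught_egg,157,0.573,0.197,0.051,0.064,0.064,0.032,0,0,0.013,0.006,0,0,0,0,0
WcE-SA-01,wild_caught_egg,51,0.569,0.137,0.059,0.059,0.098,0.078,0,0,0,0,0,0,0,0,0
WcE-An-02,wild_caught_egg,49,0.653,0.020,0.327,0,0,0,0,0,0,0,0,0,0,0,0
WcE-SA-02,wild_caught_egg,80,0.488,0.225,0.050,0.013,0.138,0.050,0,0,0.038,0,0,0,0,0,0
WcE-SA-03,wild_caught_egg,51,0.490,0.078,0.196,0.059,0.098,0.039,0,0,0.020,0,0,0.020,0,0,0
MJO-07-005,wild_caught_egg,53,0.604,0.094,0.019,0.019,0.170,0.075,0,0.019,0,0,0,0,0,0,0
MJO-07-006,wild_caught_egg,48,0.604,0.083,0.125,0.021,0.083,0.042,0,0,0,0,0,0.042,0,0,0
MJO-06-29,captive_spawned,50,0.680,0.140,0.080,0,0.060,0,0,0,0.040,0,0,0,0,0,0
Cs-01,captive_spawned,58,0.724,0.052,0,0.034,0.069,0.121,0,0,0,0,0,0,0,0,0
Cs-An-02,captive_spawned,51,0,0,1.000,0,0,0,0,0,0,0,0,0,0,0,0
Cs-SA-02,captive_spawned,53,0.434,0.075,0.170,0.132,0.170,0,0,0,0,0,0.019,0,0,0,0
Cs-04,captive_spawned,47,0.596,0.255,0.021,0,0.043,0.064,0,0,0,0,0.000,0.021,0,0,0
TFT039,captive_spawned,52,0.596,0.269,0.038,0,0.000,0.096,0,0,0,0,0.000,0,0,0,0
TFT-04-23,captive_spawned,47,0.617,0.043,0.191,0,0.000,0.043,0,0,0,0,0.000,0.106,0,0,0
TFT-04-24,captive_spawned,48,0.583,0.125,0.208,0,0.021,0.063,0,0,0,0,0.000,0,0,0,0
TFT-04-25,captive_spawned,53,0.434,0.057,0.113,0.057,0.283,0.057,0,0,0,0,0.000,0,0,0,0
TFT-04-29,captive_spawned,53,0.566,0.245,0,0.075,0,0.094,0,0,0.019,0,0.000,0,0,0,0
TFT-04-30,captive_spawned,45,0.400,0.333,0,0,0,0.244,0,0,0,0,0.022,0,0,0,0
TFT-04-31,captive_spawned,50,0.420,0.340,0.020,0,0.060,0.040,0,0,0.100,0,0,0.020,0,0,0
TFT-05-006,captive_spawned,50,0.500,0.360,0.020,0,0.020,0.080,0,0,0.020,0,0,0,0,0,0
TFT-05-007,captive_spawned,48,0.625,0.292,0.021,0.063,0,0.000,0,0,0,0,0,0,0,0,0
TFT-05-008,captive_spawned,49,0.592,0.082,0,0.102,0,0.224,0,0,0,0,0,0,0,0,0
TFT-05-009,captive_spawned,50,0.680,0.160,0,0,0,0.120,0,0,0.040,0,0,0,0,0,0
TFT-05-011,captive_spawned,53,0.623,0.057,0.113,0.019,0.170,0,0,0,0.019,0,0,0,0,0,0
MJO-06-25,captive_spawned,49,0.551,0.245,0.061,0,0.061,0.082,0,0,0,0,0,0,0,0,0
MJO-06-028,captive_spawned,50,0.400,0.140,0.220,0,0.220,0.020,0,0,0,0,0,0,0,0,0
MJO-07-007,captive_spawned,50,0.560,0.020,0.120,0.280,0.020,0,0,0,0,0,0,0,0,0,0
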