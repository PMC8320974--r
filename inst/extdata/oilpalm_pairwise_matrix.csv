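Population,596,597,598,599,600,601,602,603,604,605,606,607
596,0.000,0.111,0.081,0.078,0.084,0.097,0.073,0.084,0.128,0.079,0.066,0.112
597,0.462,0.000,0.139,0.115,0.132,0.177,0.136,0.143,0.195,0.144,0.126,0.166
598,0.321,0.522,0.000,0.094,0.119,0.096,0.117,0.072,0.182,0.136,0.107,0.146
599,0.388,0.505,0.392,0.000,0.077,0.123,0.090,0.111,0.158,0.109,0.084,0.119
600,0.379,0.553,0.497,0.349,0.000,0.121,0.076,0.125,0.153,0.102,0.095,0.136
601,0.344,0.698,0.292,0.493,0.454,0.000,0.115,0.092,0.185,0.142,0.117,0.174
602,0.293,0.536,0.465,0.396,0.293,0.397,0.000,0.116,0.137,0.092,0.083,0.099
603,0.342,0.560,0.242,0.500,0.539,0.281,0.454,0.000,0.173,0.126,0.108,0.150
604,0.430,0.680,0.637,0.603,0.545,0.577,0.425,0.596,0.000,0.123,0.125,0.202
605,0.348,0.591,0.595,0.527,0.439,0.537,0.359,0.534,0.362,0.000,0.075,0.142
606,0.312,0.560,0.470,0.432,0.451,0.465,0.357,0.487,0.412,0.318,0.000,0.117
607,0.424,0.599,0.531,0.478,0.533,0.602,0.333,0.555,0.669,0.544,0.458,0.000
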