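variable,Sex,Age,PHQ,BISA,BISM,BISN,BIST,NAt,AcL,InI,Alc,Mrh,Drg,Aff,Anx,AlA,DrA,ADH,CnO,Psy,Etn,Adj,EmA,PhA,SxA,EmN,PhN,SDQT,SDQE,SDQC,SDQH,SDQPer,SDQPrs,Mgr
Sex,1.000,0.197,-0.129,-0.033,-0.008,-0.003,-0.016,-0.092,0.060,-0.084,-0.058,0.134,-0.024,-0.063,-0.102,0.009,0.117,0.203,0.093,-0.001,-0.143,0.068,-0.138,0.046,-0.112,-0.046,-0.026,-0.113,-0.173,-0.015,0.041,-0.134,-0.055,-0.014
Age,0.197,1.000,-0.017,0.107,-0.018,-0.097,0.002,-0.044,0.002,-0.062,0.014,0.054,-0.045,0.021,-0.046,0.030,0.125,-0.032,-0.033,0.007,0.019,-0.146,0.035,0.100,-0.023,-0.044,0.033,-0.140,-0.053,-0.081,-0.160,-0.059,0.086,0.104
PHQ,-0.129,-0.017,1.000,0.002,0.184,-0.001,0.140,0.245,-0.089,0.156,0.021,0.054,0.103,0.191,0.106,0.093,0.007,0.004,-0.097,-0.049,0.167,-0.008,0.311,0.121,0.147,0.218,0.148,0.470,0.526,0.118,0.223,0.271,-0.022,0.128
BISA,-0.033,0.107,0.002,1.000,0.093,-0.305,0.473,0.017,0.021,0.106,0.035,-0.129,-0.058,0.114,0.082,0.114,0.010,-0.064,-0.035,-0.027,0.012,0.160,0.010,-0.033,-0.070,-0.220,-0.137,-0.231,-0.043,-0.128,-0.277,-0.103,0.177,-0.124
BISM,-0.008,-0.018,0.184,0.093,1.000,-0.094,0.704,0.157,-0.046,0.070,0.158,0.034,0.075,0.063,0.057,0.114,0.061,0.009,0.053,-0.035,0.067,0.126,0.054,0.110,0.044,-0.065,-0.104,0.317,0.176,0.288,0.222,0.067,0.050,-0.086
BISN,-0.003,-0.097,-0.001,-0.305,-0.094,1.000,0.310,0.089,-0.083,0.025,-0.047,0.035,0.015,-0.035,-0.016,-0.023,0.014,-0.046,-0.043,0.001,-0.045,-0.111,0.040,0.053,0.039,0.115,0.098,0.106,-0.023,0.037,0.194,0.055,-0.028,0.192
BIST,-0.016,0.002,0.140,0.473,0.704,0.310,1.000,0.144,-0.087,0.117,0.081,-0.040,0.033,0.079,0.049,0.155,0.066,-0.060,0.005,-0.071,-0.005,0.142,0.054,0.062,0.019,-0.128,-0.099,0.151,0.082,0.155,0.105,0.025,0.098,-0.049
NAt,-0.092,-0.044,0.245,0.017,0.157,0.089,0.144,1.000,0.044,0.176,0.038,0.025,0.106,0.152,0.081,0.033,0.053,-0.070,0.113,0.002,0.198,-0.059,0.261,0.242,0.222,0.088,0.180,0.192,0.155,0.083,0.065,0.161,0.050,0.163
AcL,0.060,0.002,-0.089,0.021,-0.046,-0.083,-0.087,0.044,1.000,0.145,-0.035,0.071,0.039,0.141,0.068,0.023,-0.019,-0.021,-0.008,-0.093,0.103,-0.047,-0.044,-0.014,-0.053,-0.001,0.017,-0.038,0.019,0.039,-0.083,-0.047,-0.035,0.005
InI,-0.084,-0.062,0.156,0.106,0.070,0.025,0.117,0.176,0.145,1.000,0.037,-0.054,-0.064,0.261,0.159,0.132,0.095,-0.180,-0.049,-0.022,0.178,-0.004,0.151,0.151,0.119,0.075,0.145,0.067,0.076,0.032,0.034,0.014,0.066,0.130
Alc,-0.058,0.014,0.021,0.035,0.158,-0.047,0.081,0.038,-0.035,0.037,1.000,0.230,0.228,0.050,-0.052,0.049,0.113,-0.083,-0.068,-0.047,0.048,-0.042,-0.015,-0.010,0.088,-0.001,0.004,0.032,0.014,0.094,0.051,-0.016,0.017,0.097
Mrh,0.134,0.054,0.054,-0.129,0.034,0.035,-0.040,0.025,0.071,-0.054,0.230,1.000,0.283,-0.068,-0.042,0.077,0.359,-0.002,0.095,-0.038,0.061,-0.001,0.082,0.072,0.081,0.116,0.086,0.093,0.110,0.082,0.025,0.029,-0.058,0.125
Drg,-0.024,-0.045,0.103,-0.058,0.075,0.015,0.033,0.106,0.039,-0.064,0.228,0.283,1.000,-0.073,-0.034,-0.010,-0.011,-0.019,-0.016,-0.011,-0.032,-0.028,0.000,0.030,0.037,0.000,0.020,0.105,0.100,0.101,-0.003,0.089,-0.081,0.128
Aff,-0.063,0.021,0.191,0.114,0.063,-0.035,0.079,0.152,0.141,0.261,0.050,-0.068,-0.073,1.000,0.338,0.222,0.160,0.008,-0.026,0.063,0.173,-0.114,0.090,0.067,0.058,0.006,0.020,0.093,0.091,0.036,-0.005,0.106,0.035,0.061
Anx,-0.102,-0.046,0.106,0.082,0.057,-0.016,0.049,0.081,0.068,0.159,-0.052,-0.042,-0.034,0.338,1.000,0.179,0.044,0.049,0.034,0.059,0.183,0.029,0.041,0.004,0.018,-0.029,0.001,0.173,0.201,-0.002,-0.025,0.217,-0.064,0.044
AlA,0.009,0.030,0.093,0.114,0.114,-0.023,0.155,0.033,0.023,0.132,0.049,0.077,-0.010,0.222,0.179,1.000,0.495,-0.051,0.251,-0.029,-0.029,0.114,0.004,-0.029,-0.021,0.003,-0.013,0.073,-0.010,-0.001,0.075,0.079,0.048,-0.019
DrA,0.117,0.125,0.007,0.010,0.061,0.014,0.066,0.053,-0.019,0.095,0.113,0.359,-0.011,0.160,0.044,0.495,1.000,-0.058,0.129,0.087,0.051,0.082,0.006,0.041,0.039,0.040,0.042,0.051,0.008,-0.021,0.055,0.116,-0.015,0.070
ADH,0.203,-0.032,0.004,-0.064,0.009,-0.046,-0.060,-0.070,-0.021,-0.180,-0.083,-0.002,-0.019,0.008,0.049,-0.051,-0.058,1.000,-0.022,-0.054,-0.031,0.040,-0.080,-0.081,-0.021,-0.102,-0.046,0.014,-0.035,0.012,0.151,-0.045,0.002,-0.080
CnO,0.093,-0.033,-0.097,-0.035,0.053,-0.043,0.005,0.113,-0.008,-0.049,-0.068,0.095,-0.016,-0.026,0.034,0.251,0.129,-0.022,1.000,-0.045,-0.054,0.052,0.048,0.120,0.082,0.015,0.080,0.118,-0.135,0.193,0.111,0.054,0.045,-0.082
Psy,-0.001,0.007,-0.049,-0.027,-0.035,0.001,-0.071,0.002,-0.093,-0.022,-0.047,-0.038,-0.011,0.063,0.059,-0.029,0.087,-0.054,-0.045,1.000,-0.027,-0.079,-0.051,0.008,0.030,-0.029,0.050,-0.013,-0.065,-0.011,0.029,0.059,-0.079,0.084
Etn,-0.143,0.019,0.167,0.012,0.067,-0.045,-0.005,0.198,0.103,0.178,0.048,0.061,-0.032,0.173,0.183,-0.029,0.051,-0.031,-0.054,-0.027,1.000,-0.089,0.109,-0.011,0.038,0.081,0.064,0.059,0.102,-0.029,-0.065,0.140,0.013,-0.041
Adj,0.068,-0.146,-0.008,0.160,0.126,-0.111,0.142,-0.059,-0.047,-0.004,-0.042,-0.001,-0.028,-0.114,0.029,0.114,0.082,0.040,0.052,-0.079,-0.089,1.000,0.010,0.031,0.025,-0.067,-0.029,0.028,-0.003,0.010,0.027,0.001,-0.033,-0.037
EmA,-0.138,0.035,0.311,0.010,0.054,0.040,0.054,0.261,-0.044,0.151,-0.015,0.082,0.000,0.090,0.041,0.004,0.006,-0.080,0.048,-0.051,0.109,0.010,1.000,0.599,0.402,0.516,0.456,0.311,0.259,0.219,0.051,0.218,-0.077,0.216
PhA,0.046,0.100,0.121,-0.033,0.110,0.053,0.062,0.242,-0.014,0.151,-0.010,0.072,0.030,0.067,0.004,-0.029,0.041,-0.081,0.120,0.008,-0.011,0.031,0.599,1.000,0.425,0.340,0.448,0.252,0.150,0.227,0.095,0.113,-0.090,0.277
SxA,-0.112,-0.023,0.147,-0.070,0.044,0.039,0.019,0.222,-0.053,0.119,0.088,0.081,0.037,0.058,0.018,-0.021,0.039,-0.021,0.082,0.030,0.038,0.025,0.402,0.425,1.000,0.272,0.361,0.223,0.159,0.116,0.149,0.151,-0.055,0.148
EmN,-0.046,-0.044,0.218,-0.220,-0.065,0.115,-0.128,0.088,-0.001,0.075,-0.001,0.116,0.000,0.006,-0.029,0.003,0.040,-0.102,0.015,-0.029,0.081,-0.067,0.516,0.340,0.272,1.000,0.566,0.284,0.188,0.167,0.075,0.231,-0.152,0.234
PhN,-0.026,0.033,0.148,-0.137,-0.104,0.098,-0.099,0.180,0.017,0.145,0.004,0.086,0.020,0.020,0.001,-0.013,0.042,-0.046,0.080,0.050,0.064,-0.029,0.456,0.448,0.361,0.566,1.000,0.203,0.160,0.073,0.045,0.168,-0.089,0.250
SDQT,-0.113,-0.140,0.470,-0.231,0.317,0.106,0.151,0.192,-0.038,0.067,0.032,0.093,0.105,0.093,0.173,0.073,0.051,0.014,0.118,-0.013,0.059,0.028,0.311,0.252,0.223,0.284,0.203,1.000,0.594,0.651,0.549,0.610,-0.164,0.088
SDQE,-0.173,-0.053,0.526,-0.043,0.176,-0.023,0.082,0.155,0.019,0.076,0.014,0.110,0.100,0.091,0.201,-0.010,0.008,-0.035,-0.135,-0.065,0.102,-0.003,0.259,0.150,0.159,0.188,0.160,0.594,1.000,0.130,0.137,0.292,0.040,0.114
SDQC,-0.015,-0.081,0.118,-0.128,0.288,0.037,0.155,0.083,0.039,0.032,0.094,0.082,0.101,0.036,-0.002,-0.001,-0.021,0.012,0.193,-0.011,-0.029,0.010,0.219,0.227,0.116,0.167,0.073,0.651,0.130,1.000,0.310,0.158,-0.249,-0.019
SDQH,0.041,-0.160,0.223,-0.277,0.222,0.194,0.105,0.065,-0.083,0.034,0.051,0.025,-0.003,-0.005,-0.025,0.075,0.055,0.151,0.111,0.029,-0.065,0.027,0.051,0.095,0.149,0.075,0.045,0.549,0.137,0.310,1.000,0.001,-0.086,0.023
SDQPer,-0.134,-0.059,0.271,-0.103,0.067,0.055,0.025,0.161,-0.047,0.014,-0.016,0.029,0.089,0.106,0.217,0.079,0.116,-0.045,0.054,0.059,0.140,0.001,0.218,0.113,0.151,0.231,0.168,0.610,0.292,0.158,0.001,1.000,-0.126,0.115
SDQPrs,-0.055,0.086,-0.022,0.177,0.050,-0.028,0.098,0.050,-0.035,0.066,0.017,-0.058,-0.081,0.035,-0.064,0.048,-0.015,0.002,0.045,-0.079,0.013,-0.033,-0.077,-0.090,-0.055,-0.152,-0.089,-0.164,0.040,-0.249,-0.086,-0.126,1.000,-0.084
Mgr,-0.014,0.104,0.128,-0.124,-0.086,0.192,-0.049,0.163,0.005,0.130,0.097,0.125,0.128,0.061,0.044,-0.019,0.070,-0.080,-0.082,0.084,-0.041,-0.037,0.216,0.277,0.148,0.234,0.250,0.088,0.114,-0.019,0.023,0.115,-0.084,1.000
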