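scenario_id,station,before,after,total
0,novice_resident,32.42,27.18,59.60
0,experienced_resident,32.42,21.61,54.03
0,senior_staff,24.39,25.13,49.52
1,novice_resident,32.46,18.48,50.94
1,experienced_resident,32.46,5.21,37.67
1,senior_staff,28.32,33.74,62.06
2,novice_resident,32.41,9.22,41.63
2,experienced_resident,32.41,18.45,50.86
2,senior_staff,30.30,33.87,64.17
3,novice_resident,12.15,6.97,19.12
3,experienced_resident,12.15,9.37,21.52
3,senior_staff,51.80,33.30,85.03
4,novice_resident,32.40,27.02,59.42
4,experienced_resident,32.40,22.41,54.81
4,senior_staff,13.09,9.76,22.87
5,novice_resident,22.27,15.66,37.93
5,experienced_resident,22.27,15.25,37.52
5,senior_staff,25.75,27.70,53.45
6,novice_resident,32.35,8.68,41.03
6,experienced_resident,32.35,5.075,37.43
6,senior_staff,32.78,34.24,67.02
7,novice_resident,12.17,7.06,19.23
7,experienced_resident,12.17,10.93,23.10
7,senior_staff,15.52,14.93,30.45
8,novice_resident,22.42,5.06,27.48
8,experienced_resident,22.42,3.77,26.19
8,senior_staff,32.36,30.80,63.16
9,novice_resident,12.04,1.43,13.47
9,experienced_resident,12.04,2.46,14.50
9,senior_staff,19.68,3.53,23.21
10,novice_resident,12.10,1.96,14.06
10,experienced_resident,12.10,2.49,14.59
10,senior_staff,17.61,17.50,35.11
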