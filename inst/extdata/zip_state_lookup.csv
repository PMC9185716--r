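zip,state,lat,long
02215,MA,42.35,-71.10
02903,RI,41.82,-71.41
10001,NY,40.75,-73.99
19104,PA,39.96,-75.19
21201,MD,39.29,-76.62
30303,GA,33.75,-84.39
33101,FL,25.77,-80.19
37203,TN,36.15,-86.80
48201,MI,42.35,-83.06
55401,MN,44.98,-93.27
60601,IL,41.89,-87.62
63101,MO,38.63,-90.19
70112,LA,29.96,-90.08
75201,TX,32.78,-96.80
80202,CO,39.75,-104.99
84101,UT,40.76,-111.89
85001,AZ,33.45,-112.07
90012,CA,34.06,-118.24
97201,OR,45.51,-122.68
98101,WA,47.61,-122.33
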