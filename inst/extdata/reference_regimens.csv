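day,fluoxetine_cave,paroxetine_dose,paroxetine_cave,citalopram_dose,citalopram_cave,sertraline_dose,sertraline_cave,venlafaxine_dose,venlafaxine_cave,fluvoxamine_dose,fluvoxamine_cave
1,30.8,19.2,8.7,11.5,10.4,23.7,11.6,82.8,102.4,20.5,15.1
2,55.8,24.6,15.7,13.4,18.8,28.9,20.9,111.2,185.4,21.0,27.3
3,74.8,28.8,21.0,14.7,25.1,33.1,28.0,134.1,248.4,25.0,36.5
4,89.5,31.8,25.2,15.7,30.1,36.4,33.5,152.6,297.2,29.0,43.7
5,101.0,33.6,28.4,16.6,34.0,39.4,37.9,166.5,335.5,31.0,49.3
6,110.1,35.4,31.0,17.4,37.1,41.3,41.3,178.2,365.9,33.0,53.8
7,117.5,36.0,33.0,17.9,39.5,43.1,44.0,187.7,390.3,34.0,57.4
8,123.4,37.8,34.7,18.5,41.5,44.6,46.2,195.3,409.8,36.0,60.3
9,128.1,37.8,36.0,18.8,43.1,45.8,48.0,201.6,425.7,37.0,62.6
10,132.0,39.0,37.1,19.2,44.4,46.9,49.5,206.1,438.5,37.0,64.5
11,135.1,39.0,38.0,19.5,45.5,47.5,50.6,210.6,448.9,38.0,66.0
12,137.7,39.6,38.7,19.6,46.3,48.3,51.6,213.8,457.4,39.0,67.2
13,139.8,39.6,39.3,19.8,47.0,48.8,52.4,216.5,464.3,39.0,68.3
14,141.5,40.2,39.8,20.0,47.6,49.1,53.0,218.7,470.0,40.0,69.1
15,142.9,40.2,40.2,20.2,48.1,49.7,53.6,220.5,474.7,40.0,69.8
16,144.0,40.2,40.5,20.3,48.4,49.8,54.0,222.3,478.5,40.0,70.3
17,145.0,40.8,40.8,20.3,48.8,50.0,54.3,223.2,481.6,41.0,70.8
18,145.7,40.8,41.0,20.4,49.0,50.3,54.6,224.1,484.2,40.0,71.2
19,146.4,40.8,41.2,20.5,49.2,50.6,54.9,225.0,486.3,41.0,71.5
20,146.9,40.8,41.3,20.4,49.4,50.6,55.1,225.9,488.0,41.0,71.7
21,147.3,40.8,41.4,20.6,49.6,50.6,55.2,226.4,489.4,41.0,71.9
22,147.7,40.8,41.5,20.6,49.7,50.7,55.3,226.8,490.6,41.0,72.1
23,148.0,41.4,41.6,20.6,49.8,51.0,55.5,227.3,491.5,41.0,72.3
24,148.2,40.8,41.7,20.7,49.8,50.8,55.5,227.3,492.3,41.0,72.4
25,148.4,40.8,41.7,20.6,49.9,51.0,55.6,227.7,493.0,41.0,72.5
26,148.5,41.4,41.8,20.7,50.0,51.1,55.7,228.2,493.5,41.0,72.6
27,148.7,40.8,41.8,20.6,50.0,50.9,55.7,228.2,494.0,41.0,72.6
28,148.8,41.4,41.9,20.8,50.0,51.2,55.8,228.2,494.3,41.0,72.7
29,148.9,40.8,41.9,20.6,50.1,51.1,55.8,228.6,494.6,41.0,72.7
30,149.0,41.4,41.9,20.7,50.1,51.0,55.8,228.6,494.9,41.0,72.8
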