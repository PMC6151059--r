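patient_id,time_min,map_mmHg,hr_bpm
P0001,0,85.8,76.9
P0001,5,80.4,68.9
P0001,10,76.4,71.2
P0001,15,73.4,68.4
P0001,20,69.2,68.5
P0001,25,85.8,70.7
P0001,30,92.7,67.1
P0001,35,98.9,59.5
P0001,40,99.6,64.8
P0001,45,104.1,66.6
P0001,50,99.7,66.3
P0001,55,111.4,63.8
P0001,60,113.7,66.2
P0001,65,109.8,63.5
P0001,70,102.9,64.1
P0001,75,98.5,67.3
P0001,80,86.1,76.7
P0001,85,95.9,77.5
P0001,90,97.1,83
P0001,95,94.7,73.3
P0001,100,86.1,74.2
P0001,105,85.1,66.7
P0001,110,82.6,66.9
P0001,115,88.2,73.5
P0001,120,88.4,71.9
P0001,125,92.1,79
P0001,130,94.9,71.5
P0001,135,88.1,72.1
P0001,140,89.6,72.2
P0001,145,78.7,71.8
P0001,150,68.5,73.5
P0001,155,77.4,74.6
P0001,160,78.6,83.7
P0001,165,85.1,81.6
P0001,170,82.8,92.1
P0001,175,75.9,84.2
P0001,180,73.6,86.9
P0001,185,69.5,91.5
P0001,190,71.5,103.5
P0001,195,76.9,94.1
P0002,0,77.3,84.8
P0002,5,90.3,78.6
P0002,10,80.1,73.8
P0002,15,79.9,70.8
P0002,20,80.7,72.4
P0002,25,75.3,66.7
P0002,30,68.5,64.6
P0002,35,62.3,58.4
P0002,40,63.5,58.1
P0002,45,71.9,60.1
P0002,50,68.8,64.8
P0002,55,65.6,72.1
P0002,60,70.3,74.8
P0002,65,64.2,63.3
P0002,70,67.4,63.9
P0002,75,69.8,69.7
P0002,80,74.3,73.4
P0002,85,83.3,64.9
P0002,90,81.7,52.3
P0002,95,79.5,66.5
P0002,100,84.4,64
P0002,105,81.3,69.3
P0002,110,78.5,65
P0002,115,77.6,59.2
P0002,120,82.4,63.7
P0002,125,80.3,70.5
P0002,130,82.7,79.6
P0002,135,86.2,75.1
P0002,140,80.8,75.7
P0002,145,75.3,71
P0002,150,73.7,68
P0002,155,77.2,76.7
P0002,160,79,74.5
P0002,165,86.2,64.7
P0002,170,82.4,76.8
P0002,175,84.1,78.9
P0002,180,79.7,81.5
P0002,185,69.6,81.5
P0002,190,70.3,72.8
P0003,0,82.7,77.9
P0003,5,82.2,73.6
P0003,10,79,81.5
P0003,15,86.8,86.1
P0003,20,85.9,86
P0003,25,77.8,83.4
P0003,30,84.7,70
P0003,35,93.1,82.4
P0003,40,78.9,85.9
P0003,45,85,84.9
P0003,50,82.3,86.7
P0003,55,90,92.1
P0003,60,96.5,86.6
P0003,65,91,91
P0003,70,80.3,83.5
P0003,75,83.4,89.5
P0003,80,86.1,85.2
P0003,85,81.1,82.9
P0003,90,73.9,86.8
P0003,95,79.1,78.6
P0003,100,74.2,75.6
P0003,105,80.2,77
P0003,110,77.9,76.5
P0003,115,81.7,79.9
P0003,120,86.1,75.6
P0003,125,83.6,76.8
P0003,130,78.6,71.1
P0003,135,73.7,64.4
P0003,140,70.4,64.8
P0003,145,79,65.2
P0003,150,79.2,71.6
P0003,155,91,66.3
P0003,160,79.5,67.9
P0003,165,80.8,60.7
P0003,170,83.6,68.5
P0003,175,73.6,66.3
P0004,0,80,64.4
P0004,5,67.4,75.5
P0004,10,73.6,76.2
P0004,15,74.9,73
P0004,20,76.9,67.4
P0004,25,79.7,74
P0004,30,75.6,73.9
P0004,35,72,61.7
P0004,40,76.2,60.3
P0004,45,85.8,60.8
P0004,50,85.6,63.2
P0004,55,87.9,68
P0004,60,80.2,59.3
P0004,65,78.8,59.3
P0004,70,81.4,60
P0004,75,92.3,67.4
P0004,80,93.1,77.6
P0004,85,87.9,74.1
P0004,90,84.9,74
P0004,95,85,76.7
P0004,100,90,70.2
P0004,105,82.8,73.3
P0004,110,83.4,74
P0004,115,98.5,75
P0004,120,103.8,79.3
P0004,125,95,83.6
P0004,130,88.1,89.4
P0004,135,84.7,76.4
P0005,0,77.6,56.6
P0005,5,77.8,68.2
P0005,10,77.5,59.4
P0005,15,70.4,60.6
P0005,20,65.2,56.2
P0005,25,59.6,58.4
P0005,30,63.3,59.9
P0005,35,60.5,52.9
P0005,40,63.9,47.8
P0005,45,66.3,55.4
P0005,50,65.4,55
P0005,55,63.7,49.7
P0005,60,62.6,55.1
P0005,65,60.6,61.7
P0005,70,51.8,68.1
P0005,75,52,67
P0005,80,48.2,68.5
P0005,85,51.1,74.2
P0005,90,44.9,75.2
P0005,95,54.1,80.8
P0005,100,61.1,78.9
P0005,105,75.1,78.9
P0005,110,72.4,74.8
P0005,115,80.8,65
P0005,120,69.6,68.1
P0005,125,62,62.6
P0005,130,70.7,69.5
P0005,135,69.9,73
P0005,140,68.6,63.6
P0005,145,55.2,65.9
P0005,150,50.6,67.2
P0005,155,61.6,75.3
P0005,160,60.4,74.9
P0005,165,65.8,79
P0005,170,64.5,77.9
P0006,0,84.8,76.5
P0006,5,94.8,79.9
P0006,10,91.9,79.4
P0006,15,93.1,81.4
P0006,20,85.9,78.5
P0006,25,76.5,78.3
P0006,30,75.9,80.8
P0006,35,79,82.6
P0006,40,74,77.5
P0006,45,62.2,76.5
P0006,50,67.3,77.8
P0006,55,79.1,75.6
P0006,60,72.9,82.1
P0006,65,61.6,73
P0006,70,64.4,76
P0006,75,70.6,80.9
P0006,80,78.4,82.1
P0006,85,76.1,75.2
P0006,90,76.2,70.2
P0006,95,79.7,76.9
P0006,100,87.5,79.4
P0006,105,85.3,72.1
P0006,110,82.1,75.7
P0006,115,75.1,72.9
P0006,120,82.2,73.4
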