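age	sites	am_fraction
newborn	Femur	6.7
newborn	Humerus	4.5
newborn	Sacrum	4.4
newborn	Tibia and fibula	7.1
newborn	Pelvis	11.4
newborn	Skull	28.2
newborn	Clavicle	0.7
newborn	Scapula	2.3
newborn	Ribs	7.1
newborn	Radius and ulna	2.4
newborn	Hand and foot	10.8
newborn	Cervical vertebrae	1.7
newborn	Thoracic vertebrae	7.2
newborn	Lumbar vertebrae	5.5
1y	Femur	8.1
1y	Humerus	5.2
1y	Sacrum	5.1
1y	Tibia and fibula	8.7
1y	Pelvis	13.1
1y	Skull	28.7
1y	Clavicle	0.9
1y	Scapula	2.7
1y	Ribs	8.2
1y	Radius and ulna	2.6
1y	Cervical vertebrae	2.1
1y	Thoracic vertebrae	8.3
1y	Lumbar vertebrae	6.4
5y	Femur	13.5
5y	Humerus	4.8
5y	Sacrum	5.7
5y	Tibia and fibula	9.3
5y	Pelvis	13.5
5y	Skull	18.1
5y	Clavicle	0.9
5y	Scapula	2.8
5y	Ribs	9.1
5y	Radius and ulna	2.1
5y	Sternum	1.8
5y	Cervical vertebrae	2.3
5y	Thoracic vertebrae	9.2
5y	Lumbar vertebrae	7.0
10y	Femur	15.7
10y	Humerus	4.1
10y	Sacrum	6.8
10y	Tibia and fibula	5.6
10y	Pelvis	15.8
10y	Skull	12.8
10y	Clavicle	0.9
10y	Scapula	2.9
10y	Ribs	11.0
10y	Sternum	2.1
10y	Cervical vertebrae	2.7
10y	Thoracic vertebrae	11.0
10y	Lumbar vertebrae	8.5
15y	Femur	11.3
15y	Humerus	3.8
15y	Sacrum	8.5
15y	Pelvis	18.6
15y	Skull	10.2
15y	Clavicle	1.0
15y	Scapula	3.3
15y	Ribs	13.7
15y	Sternum	1.8
15y	Cervical vertebrae	3.3
15y	Thoracic vertebrae	13.8
15y	Lumbar vertebrae	10.6
adult	Femur	5.95
adult	Humerus	3.6
adult	Sacrum	7.48
adult	Pelvis	23.2
adult	Skull	6.2
adult	Clavicle|Scapula|Ribs	15.3
adult	Sternum	1.8
adult	Cervical vertebrae	3.5
adult	Thoracic vertebrae	17.5
adult	Lumbar vertebrae	15.5
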