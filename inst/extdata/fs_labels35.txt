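# 35-label whole-brain segmentation lookup table, standard FreeSurfer
# convention (id name R G B A).
2   Left-Cerebral-White-Matter     245 245 245 0
3   Left-Cerebral-Cortex           205 62  78  0
4   Left-Lateral-Ventricle         120 18  134 0
5   Left-Inf-Lat-Vent              196 58  250 0
7   Left-Cerebellum-White-Matter   220 248 164 0
8   Left-Cerebellum-Cortex         230 148 34  0
10  Left-Thalamus                  0   118 14  0
11  Left-Caudate                   122 186 220 0
12  Left-Putamen                   236 13  176 0
13  Left-Pallidum                  12  48  255 0
14  3rd-Ventricle                  204 182 142 0
15  4th-Ventricle                  42  204 164 0
16  Brain-Stem                     119 159 176 0
17  Left-Hippocampus               220 216 20  0
18  Left-Amygdala                  103 255 255 0
24  CSF                            60  60  60  0
26  Left-Accumbens-area            255 165 0   0
28  Left-VentralDC                 165 42  42  0
31  Left-choroid-plexus            0   200 200 0
41  Right-Cerebral-White-Matter    245 245 245 0
42  Right-Cerebral-Cortex          205 62  78  0
43  Right-Lateral-Ventricle        120 18  134 0
44  Right-Inf-Lat-Vent             196 58  250 0
46  Right-Cerebellum-White-Matter  220 248 164 0
47  Right-Cerebellum-Cortex        230 148 34  0
49  Right-Thalamus                 0   118 14  0
50  Right-Caudate                  122 186 220 0
51  Right-Putamen                  236 13  176 0
52  Right-Pallidum                 13  48  255 0
53  Right-Hippocampus              220 216 20  0
54  Right-Amygdala                 103 255 255 0
58  Right-Accumbens-area           255 165 0   0
60  Right-VentralDC                165 42  42  0
63  Right-choroid-plexus           0   200 221 0
77  WM-hypointensities             200 70  255 0
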