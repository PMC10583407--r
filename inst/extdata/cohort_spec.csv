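index,test,kind,mean_drivable,sd_drivable,mean_undrivable,sd_undrivable,prop_drivable,prop_undrivable,source
Digit span forward,CAT,continuous,5.6,0.1,5.4,1.0,,,published
Digit span backward,CAT,continuous,4.0,1.5,3.7,0.8,,,published
Tapping span forward,CAT,continuous,5.9,1.3,4.8,1.7,,,published
Tapping span backward,CAT,continuous,5.4,1.4,4.4,1.5,,,published
Visual cancellation Kana time,CAT,continuous,146.7,36.7,141.8,42.7,,,published
Visual cancellation triangle time,CAT,continuous,67.8,20.7,77.2,32.6,,,published
Visual cancellation star time,CAT,continuous,77.1,21.5,80.8,16.0,,,published
Visual cancellation figure time,CAT,continuous,120.3,34.0,119.9,39.1,,,published
Visual cancellation Kana accuracy,CAT,continuous,95.9,5.3,85.8,20.0,,,published
Visual cancellation Kana hit rate,CAT,continuous,99.7,1.5,99.2,2.5,,,published
Visual cancellation triangle accuracy,CAT,continuous,98.5,2.0,93.3,15.0,,,published
Visual cancellation triangle hit rate,CAT,continuous,99.6,1.2,97.2,6.8,,,published
Visual cancellation star accuracy,CAT,continuous,99.3,1.7,93.1,17.9,,,published
Visual cancellation star hit rate,CAT,continuous,99.6,1.1,98.7,4.9,,,published
Visual cancellation figure accuracy,CAT,continuous,99.0,1.4,92.3,20.9,,,published
Visual cancellation figure hit rate,CAT,continuous,99.9,0.2,99.7,1.1,,,published
SDMT number of wrong answers,CAT,continuous,1.2,2.1,1.1,1.9,,,published
SDMT achievement rate,CAT,continuous,34.7,9.3,27.6,11.3,,,published
Memory updating 3 span accuracy,CAT,continuous,62.5,22.1,53.6,18.0,,,published
PASAT 2 seconds accuracy,CAT,continuous,47.5,17.5,40.3,14.7,,,published
Position stroop accuracy,CAT,continuous,97.7,3.7,92.8,15.6,,,published
Position stroop time,CAT,continuous,110.2,28.0,130.6,63.6,,,published
CPTAX accuracy,CAT,continuous,95.1,7.8,89.7,11.7,,,published
CPTAX hit rate,CAT,continuous,91.1,12.1,83.6,18.5,,,published
CPTAX average reaction time,CAT,continuous,578.9,93.1,601.6,74.1,,,published
CPTAX coefficient of validation,CAT,continuous,17.3,4.3,17.9,5.5,,,published
CPTSRT accuracy,CAT,continuous,98.3,1.9,88.5,16.6,,,published
CPTSRT hit rate,CAT,continuous,98.9,1.4,91.8,15.7,,,published
CPTSRT average reaction time,CAT,continuous,362.0,70.2,456.5,127.4,,,published
CPTSRT coefficient of validation,CAT,continuous,21.7,6.8,20.7,6.7,,,published
CPTX accuracy,CAT,continuous,98.3,3.9,88.6,13.9,,,published
CPTX hit rate,CAT,continuous,96.5,5.9,86.4,19.3,,,published
CPTX average reaction time,CAT,continuous,549.0,78.9,610.8,103.6,,,published
CPTX coefficient of validation,CAT,continuous,14.6,4.7,15.6,3.9,,,published
RBMT profile,RBMT,continuous,20.2,3.5,17.4,3.3,,,published
MMSE: Orientation-time,MMSE,continuous,4.9,0.4,4.0,1.0,,,published
MMSE: Orientation-location,MMSE,continuous,4.8,0.5,4.7,0.5,,,published
MMSE: Attention and calculation,MMSE,continuous,3.9,1.7,3.6,1.6,,,published
MMSE: Recall,MMSE,continuous,2.6,0.6,2.7,0.6,,,published
MMSE: Naming,MMSE,continuous,2.0,0.3,2.0,0.0,,,published
MMSE: Repetition,MMSE,binary,,,,,0.927,1.0,published
MMSE: 3-stage command,MMSE,continuous,3.0,0.2,3.0,0.0,,,published
MMSE: Writing,MMSE,binary,,,,,0.927,0.857,published
MMSE: Copying,MMSE,binary,,,,,0.829,0.786,published
MMSE total score,MMSE,continuous,27.7,2.6,26.7,2.9,,,published
JPSS total score,JPSS,continuous,19.7,6.1,21.6,5.5,,,published
Upper limbs on discharge,BRS,continuous,5.5,0.8,4.9,1.3,,,synthetic
Fingers on discharge,BRS,continuous,5.3,1.0,4.7,1.5,,,synthetic
Lower limbs on discharge,BRS,continuous,5.6,0.7,5.1,1.2,,,synthetic
Dominant side Left,BRS,binary,,,,,0.122,0.0,published
Dominant side Right,BRS,binary,,,,,0.927,1.0,published
Affected side Left,BRS,binary,,,,,0.415,0.786,published
Affected side Right,BRS,binary,,,,,0.585,0.214,published
Line crossing test,BIT,continuous,36.0,0.2,35.9,0.5,,,published
Letter cancellation test,BIT,continuous,38.0,2.4,35.6,4.4,,,published
Star cancellation test,BIT,continuous,53.6,0.7,50.3,7.4,,,published
Copying test,BIT,continuous,3.7,0.6,2.4,1.5,,,published
Line bisection test,BIT,continuous,8.9,0.5,7.9,2.5,,,published
Drawing test,BIT,continuous,2.9,0.6,2.5,0.9,,,published
BIT conventional subtest,BIT,continuous,142.9,3.2,134.6,13.7,,,published
BIT behavioral subtest,BIT,continuous,79.1,2.5,74.4,14.7,,,published
Depression score,HADS,continuous,4.3,3.5,6.6,3.3,,,published
Anxiety score,HADS,continuous,5.3,3.5,5.3,3.1,,,published
Apathy score,AS,continuous,11.4,5.5,12.5,6.9,,,published
TMT part A time,TMT,continuous,51.8,22.2,82.9,65.9,,,published
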