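# Reconstructed (synthetic) scenario calibrated so its exact per-dose
# mean nTTP matches benchmark pattern F; not the original unpublished
# grade-probability matrices.
toxicities:
- name: renal
  probs:
  - - 0.88391067667559
    - 0.094840919289368
    - 0.017672646600013
    - 0.00298291926909
    - 0.000592838165939
  - - 0.762308091475124
    - 0.188677073746098
    - 0.040567117862323
    - 0.007041402329809
    - 0.001406314586647
  - - 0.585972216854749
    - 0.309447665448917
    - 0.085639778850885
    - 0.015759230083139
    - 0.003181108762311
  - - 0.359935588260492
    - 0.412893676682075
    - 0.180833147229802
    - 0.038369860012988
    - 0.007967727814643
  - - 0.207385999716497
    - 0.405449159839695
    - 0.292609890581107
    - 0.077585832087754
    - 0.016969117774947
  - - 0.137325370248956
    - 0.353254613945321
    - 0.36291943611862
    - 0.118910347340619
    - 0.027590232346484
- name: neurological
  probs:
  - - 0.88391067667559
    - 0.094840919289368
    - 0.017672646600013
    - 0.00298291926909
    - 0.000592838165939
  - - 0.762308091475124
    - 0.188677073746098
    - 0.040567117862323
    - 0.007041402329809
    - 0.001406314586647
  - - 0.585972216854749
    - 0.309447665448917
    - 0.085639778850885
    - 0.015759230083139
    - 0.003181108762311
  - - 0.359935588260492
    - 0.412893676682075
    - 0.180833147229802
    - 0.038369860012988
    - 0.007967727814643
  - - 0.207385999716497
    - 0.405449159839695
    - 0.292609890581107
    - 0.077585832087754
    - 0.016969117774947
  - - 0.137325370248956
    - 0.353254613945321
    - 0.36291943611862
    - 0.118910347340619
    - 0.027590232346484
- name: hematological
  probs:
  - - 0.88391067667559
    - 0.094840919289368
    - 0.017672646600013
    - 0.00298291926909
    - 0.000592838165939
  - - 0.762308091475124
    - 0.188677073746098
    - 0.040567117862323
    - 0.007041402329809
    - 0.001406314586647
  - - 0.585972216854749
    - 0.309447665448917
    - 0.085639778850885
    - 0.015759230083139
    - 0.003181108762311
  - - 0.359935588260492
    - 0.412893676682075
    - 0.180833147229802
    - 0.038369860012988
    - 0.007967727814643
  - - 0.207385999716497
    - 0.405449159839695
    - 0.292609890581107
    - 0.077585832087754
    - 0.016969117774947
  - - 0.137325370248956
    - 0.353254613945321
    - 0.36291943611862
    - 0.118910347340619
    - 0.027590232346484
true_rd: 4
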