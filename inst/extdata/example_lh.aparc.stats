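# Table of FreeSurfer cortical parcellation anatomical statistics
# (synthetic example file illustrating the aparc.stats layout)
# anatomy_type surface
# hemi lh
# Measure Cortex, MeanThickness, Mean Thickness, 2.4817, mm
# NTableCols 10
# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd MeanCurv GausCurv FoldInd CurvInd
bankssts                 1538   1040  2733  2.461 0.450 0.117 0.026 13  1.9
caudalanteriorcingulate   896    597  1588  2.587 0.601 0.132 0.025  9  1.1
caudalmiddlefrontal      3474   2351  6515  2.518 0.481 0.125 0.028 31  4.1
cuneus                   2195   1459  2788  1.812 0.421 0.141 0.030 26  2.7
entorhinal                606    418  1832  3.301 0.738 0.120 0.030  4  0.8
fusiform                 4714   3203 10050  2.712 0.517 0.133 0.031 51  6.3
inferiorparietal         6965   4712 12720  2.409 0.468 0.125 0.026 71  7.5
inferiortemporal         4850   3317 10870  2.713 0.587 0.125 0.030 51  6.4
lateraloccipital         7003   4565 10970  2.104 0.449 0.139 0.031 77  9.1
superiorfrontal         10894   7556 22720  2.695 0.513 0.124 0.027 96 12.2
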