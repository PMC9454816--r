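# Per-rule contingency counts of the 92-smear oral screening study,
# encoded at count level from the published accuracy table (the per-slide
# raw data are not public; this fixture reproduces the printed
# numerators/denominators, not slide-level overlaps).
# Standards: original follow-up = 20 positive / 72 negative slides;
# modified follow-up = 25 / 67 (five discordant DNA-aneuploid slides
# re-rated as correct positive).
standard,rule,tp,fn,tn,fp
original,single_cell_9cEE,4,16,69,3
original,stemline,6,14,70,2
original,aneuploidy,7,13,68,4
original,abnormal_gt5,10,10,67,5
original,abnormal_gt4,12,8,66,6
original,aneuploidy_or_gt5,11,9,67,5
original,aneuploidy_or_gt4,13,7,66,6
original,cytology,16,4,54,18
modified,single_cell_9cEE,7,18,67,0
modified,stemline,8,17,67,0
modified,aneuploidy,11,14,67,0
modified,abnormal_gt5,15,10,67,0
modified,abnormal_gt4,17,8,66,1
modified,aneuploidy_or_gt5,16,9,67,0
modified,aneuploidy_or_gt4,18,7,66,1
modified,cytology,18,7,51,16
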