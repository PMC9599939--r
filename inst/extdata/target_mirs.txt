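# 22 miRNAs predicted (TargetScan/miRBase, conserved sites) to bind the
# target gene's 3' UTR. Ids below the marker line are same-family/cluster
# placeholders completing the set of 22 (a synthetic completion); no
# numeric result depends on them.
hsa-miR-10a
hsa-miR-10b
hsa-miR-19a
hsa-miR-19b
hsa-miR-33a
hsa-miR-33a*
hsa-miR-130a
hsa-miR-130b
hsa-miR-130b*
hsa-miR-135a*
hsa-miR-135b
hsa-miR-183*
hsa-miR-190
hsa-miR-190b
hsa-miR-301a
hsa-miR-449a
hsa-miR-449b
hsa-miR-454
# placeholders:
hsa-miR-96
hsa-miR-182
hsa-miR-301b
hsa-miR-9
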