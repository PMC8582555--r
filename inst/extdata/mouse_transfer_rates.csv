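# Whole-body mouse transfer rates (1/h): systemic exchange with blood plus
# the alimentary chain; excretion via colon->excretion is the only sink.
donor,receptor,rate_per_h
tumor,blood,327.4
blood,tumor,40.06
liver,blood,0.1159
blood,liver,5.067e-4
spleen,blood,9.78e-4
blood,spleen,1.409e-5
kidneys,blood,3.804
blood,kidneys,15.66
colon,blood,0.7151
blood,colon,689.6
stomach,blood,7.411
blood,stomach,896.0
lungs,blood,1.903
blood,lungs,148.5
small_intestine,blood,68.93
blood,small_intestine,59.41
muscle,blood,194.2
blood,muscle,62.39
bone,blood,62.6
blood,bone,38.58
skin,blood,9.38
blood,skin,27.58
brain,blood,5.439
blood,brain,795.6
heart,blood,2.416
blood,heart,490.5
liver,small_intestine,4.947e-4
stomach,small_intestine,64.71
small_intestine,colon,3.447
colon,excretion,4.244e-3
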