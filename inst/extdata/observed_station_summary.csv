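station,mean,sd,reported_simulated_mean,reported_p_value
registration,1.5,1.96,1.462,0.672
cash,0.7,1.02,0.705,0.749
novice_resident,60.67,49.89,59.602,0.561
experienced_resident,54.89,44.27,54.027,0.566
senior_staff,56.91,46.68,49.522,0.654
paraclinic,42.69,21.66,41.192,0.279
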