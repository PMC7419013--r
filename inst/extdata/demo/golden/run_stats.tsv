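metric	value
n_treated	       10
n_untreated	        2
candidate_pool_size	       10
noise_pool_size	        0
snp_masked_sites	        0
sequenced	    99321
depth_pass	    87310
ratio_pass	       73
in_pool	       66
after_noise	       66
candidates	       66
hb_pass	       66
false_positive_detection_rate	        0
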