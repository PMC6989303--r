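# Published stepping-stone marginal log-likelihoods for the four-state
# (S/P/UM/MM) model comparison of primate social organization (362
# species, dated molecular phylogeny).
model	rank	n_params	marginal_logL
RJ_DERIVED	1	6	-133.43
SYM	2	6	-140.24
IC	3	6	-140.95
ARD	4	12	-145.16
ER	5	1	-146.24
SHULTZ	6	4	-159.21
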