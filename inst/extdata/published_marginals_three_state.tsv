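# Published stepping-stone marginal log-likelihoods for the three-state
# (S/P/G) model comparison of primate social organization (362 species,
# dated molecular phylogeny). Inputs to log Bayes factor arithmetic.
model	rank	n_params	marginal_logL
IC	1	4	-79.07
SYM	2	3	-80.47
ER	3	1	-81.93
ARD	4	6	-83.45
SHULTZ_MODIFIED	5	2	-103.49
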