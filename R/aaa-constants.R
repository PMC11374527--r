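# Package-wide constants (this file loads before the modules that use them).

# covariate columns carried on every event-record row
COV_COLS <- c("WT", "ALB", "AGE", "LYM", "GVHDL", "GVHDS", "GVHDI")

# duration of a 30-minute infusion in days (zero-order input)
INFUSION_30MIN <- 1 / 48
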