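# shared constants; filename keeps them first in the collation order because
# several files use them in top-level default tables

TASKS <- c("stroop", "np", "flanker")
GROUPS <- c("simulator", "attention", "control")
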