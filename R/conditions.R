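# Structured conditions: every domain failure carries a "faz_*" class so
# callers (and the pipeline drivers) can branch on them.

faz_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "faz_error")))
}

faz_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "faz_warning")))
}
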