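# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# drop NULLs from a list
compact <- function(x) x[!vapply(x, is.null, logical(1))]
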