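# Save/restore the global RNG state so seeded package functions do not
# disturb the caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Format numeric columns with full precision but stable text representation
# for TSV output (deterministic across runs).
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], format = "g", digits = 15)
    }
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
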