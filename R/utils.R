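# internal error constructors: every user-facing failure carries a
# diabtraj_* condition class so callers can test for the failure mode
stop_diabtraj <- function(message, class, call = rlang::caller_env()) {
  rlang::abort(message, class = c(paste0("diabtraj_", class), "diabtraj_error"))
}

stop_config <- function(message) stop_diabtraj(message, "config_error")
stop_domain <- function(message) stop_diabtraj(message, "domain_error")
stop_contract <- function(message) stop_diabtraj(message, "contract_error")
stop_schema <- function(message) stop_diabtraj(message, "schema_error")
stop_parse <- function(message) stop_diabtraj(message, "parse_error")
stop_model <- function(message) stop_diabtraj(message, "model_error")
stop_classification <- function(message) stop_diabtraj(message, "classification_error")
stop_not_implemented <- function(message) stop_diabtraj(message, "not_implemented")

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

require_columns <- function(data, cols, where) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop_contract(sprintf(
      "%s is missing required column(s): %s",
      where, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
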