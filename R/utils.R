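# Internal condition helpers and RNG scoping.

dida_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "dida_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_input  <- function(msg) dida_stop(msg, "dida_input_error")
stop_format <- function(msg) dida_stop(msg, "dida_format_error")
stop_config <- function(msg) dida_stop(msg, "dida_config_error")
stop_range  <- function(msg) dida_stop(msg, "dida_range_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Hash a configuration list
#'
#' Serializes a configuration to canonical (sorted-key) JSON and returns its
#' MD5 digest. Recorded in run artifacts so that any change to a threshold or
#' path changes the recorded hash.
#'
#' @param config A list of configuration values.
#' @return A length-1 character MD5 digest.
#' @export
config_hash <- function(config) {
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x))) lapply(x[order(names(x))], sort_rec)
    else x
  }
  js <- jsonlite::toJSON(sort_rec(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}
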