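#' Write / read model parameters as a plain-text key-value config
#'
#' One `key = value` pair per line; `#` starts a comment. The object class
#' is stored under the reserved key `.class` so [read_params()] can
#' reconstruct `telegraph_params`, `hill_params` or `mechanistic_params`
#' objects.
#'
#' @param par a parameter object (or plain named list of scalars).
#' @param path output file.
#' @return `write_params`: the path, invisibly. `read_params`: the
#'   reconstructed object.
#' @export
write_params <- function(par, path) {
  cls <- class(par)[1]
  keys <- names(unclass(par))
  vals <- unclass(par)
  lines <- c(sprintf(".class = %s", cls),
             vapply(keys, function(k)
               sprintf("%s = %.17g", k, as.numeric(vals[[k]])),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  cls <- vals[keys == ".class"]
  out <- as.list(as.numeric(vals[keys != ".class"]))
  names(out) <- keys[keys != ".class"]
  switch(cls,
    telegraph_params = telegraph_params(out$k_on, out$k_off, out$mu,
                                        out$delta),
    hill_params = hill_params(out$kon0, out$kon1, out$c, out$h),
    mechanistic_params = mechanistic_params(out$k_close, out$k_far,
                                            out$k_forward, out$k_back,
                                            out$n, out$kon_basal,
                                            out$kon_enh, out$k_off, out$mu,
                                            out$delta),
    out)
}

#' Write / read a count pmf as two-column TSV
#'
#' Columns `count` and `probability`.
#'
#' @param p probability vector over counts `0..length(p)-1`.
#' @param path file path.
#' @return `write_pmf`: the path, invisibly. `read_pmf`: the probability
#'   vector.
#' @export
write_pmf <- function(p, path) {
  utils::write.table(
    data.frame(count = seq_along(p) - 1L, probability = as.numeric(p)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  df <- utils::read.delim(path)
  p <- df$probability
  structure(p, class = "count_pmf")
}

#' Write / read a simulated trajectory as TSV
#'
#' Tab-separated columns `time`, `contact`, `step`, `promoter`, `m`,
#' preceded by comment lines recording the seed and burn-in.
#'
#' @param sim a [gillespie_simulate()] result with a recorded trajectory.
#' @param path file path.
#' @return `write_trajectory`: the path, invisibly. `read_trajectory`: a
#'   data.frame with the seed attached as attribute `seed`.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "mech_trajectory"))
  if (is.null(sim$trajectory)) stop("trajectory was not recorded")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seed = %d", sim$seed),
               sprintf("# burn_in = %.17g", sim$burn_in)), con)
  utils::write.table(sim$trajectory, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 2)
  df <- utils::read.delim(path, comment.char = "#")
  attr(df, "seed") <- as.integer(sub(".*= ", "", header[1]))
  df
}

#' Convert rates from mRNA-lifetime units to per-hour
#'
#' All model rates are expressed per mRNA lifetime (`delta = 1`). For
#' display they can be converted to inverse hours assuming a lifetime,
#' by default 1.5 h.
#'
#' @param rate rate(s) in mRNA-lifetime units.
#' @param lifetime_hours assumed mRNA lifetime in hours (default 1.5).
#' @return Rates per hour.
#' @export
rate_per_hour <- function(rate, lifetime_hours = 1.5) {
  rate / lifetime_hours
}
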