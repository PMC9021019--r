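#' Configuration of a synthetic mobilization-screen study
#'
#' Defines the study conditions emulated by the generator: a single TAD of
#' ~560 kb inside a larger captured region, a promoter viewpoint inside
#' the TAD, a power-law decay of contact probability from ~1 next to the
#' promoter to ~0.05 at the TAD boundaries with an additional ~3-fold drop
#' across them, 135 insertion lines (99% inside the TAD), 3 replicate
#' expression measurements per line with 10% multiplicative noise, and 6
#' smFISH lines of 300 cells each. The ground-truth expression model is
#' either the Hill-modulated (phenomenological) or the apparent two-state
#' model.
#'
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @param chrom,region_start,region_end captured region (bp).
#' @param tad_start,tad_end TAD interval (bp).
#' @param promoter promoter / viewpoint coordinate (bp).
#' @param binsize contact-map bin size (bp).
#' @param decay_exponent power-law exponent of contact decay with distance.
#' @param boundary_factor fold drop of contacts across each TAD boundary.
#' @param count_scale expected contact count in the bins adjacent to the
#'   viewpoint (sets the Poisson sampling depth).
#' @param n_lines number of insertion lines.
#' @param inside_fraction fraction of insertions landing inside the TAD.
#' @param n_promoter_only number of promoter-only control lines (p_c = 0).
#' @param replicate_cv multiplicative (log-normal) noise CV of replicate
#'   expression means.
#' @param n_rep replicate measurements per line.
#' @param n_fish number of smFISH lines.
#' @param cells_per_line cells measured per smFISH line.
#' @param model ground-truth model: `"phenomenological"` or `"apparent"`.
#' @param truth named list of ground-truth parameters; defaults represent
#'   a strong enhancer spanning a ~5-60 mRNA dynamic range with bursting
#'   on the minutes scale (in mRNA-lifetime units): for the
#'   phenomenological model `kon0 = 0.15`, `kon1 = 2`, `k_off = 10`,
#'   `mu = 360`, `c = 0.25`, `h = 2.8`; for the apparent model the same
#'   rates with `beta = 7`, `n = 5`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed,
                         chrom = "chrSim", region_start = 0,
                         region_end = 1.6e6,
                         tad_start = 520e3, tad_end = 1.08e6,
                         promoter = 800e3, binsize = 6400,
                         decay_exponent = 0.8, boundary_factor = 3,
                         count_scale = 2000,
                         n_lines = 135L, inside_fraction = 0.99,
                         n_promoter_only = 3L,
                         replicate_cv = 0.1, n_rep = 3L,
                         n_fish = 6L, cells_per_line = 300L,
                         model = c("phenomenological", "apparent"),
                         truth = NULL) {
  if (missing(seed)) stop("a study seed is mandatory")
  model <- match.arg(model)
  if (is.null(truth)) {
    truth <- if (model == "phenomenological")
      list(kon0 = 0.15, kon1 = 2, k_off = 10, mu = 360, c = 0.25, h = 2.8)
    else
      list(kon_basal = 0.15, kon_enh = 2, k_off = 10, mu = 360, beta = 7,
           n = 5L)
  }
  stopifnot(region_start < tad_start, tad_start < promoter,
            promoter < tad_end, tad_end < region_end,
            inside_fraction >= 0, inside_fraction <= 1)
  structure(list(seed = as.integer(seed), chrom = chrom,
                 region_start = region_start, region_end = region_end,
                 tad_start = tad_start, tad_end = tad_end,
                 promoter = promoter, binsize = binsize,
                 decay_exponent = decay_exponent,
                 boundary_factor = boundary_factor,
                 count_scale = count_scale, n_lines = as.integer(n_lines),
                 inside_fraction = inside_fraction,
                 n_promoter_only = as.integer(n_promoter_only),
                 replicate_cv = replicate_cv, n_rep = as.integer(n_rep),
                 n_fish = as.integer(n_fish),
                 cells_per_line = as.integer(cells_per_line),
                 model = model, truth = truth),
            class = "study_config")
}

# independent substream seeds derived from the study seed
.substream_seeds <- function(seed) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  names(s) <- c("matrix", "insertions", "screen", "fish")
  s
}

# true contact probability between the promoter and a coordinate:
# power-law decay calibrated to 1 in the adjacent bin, attenuated by
# boundary_factor for each TAD boundary crossed
.true_pc <- function(cfg, coord) {
  d <- pmax(abs(coord - cfg$promoter), cfg$binsize / 2)
  p <- pmin((d / cfg$binsize)^(-cfg$decay_exponent), 1)
  cross <- (coord < cfg$tad_start) + (coord > cfg$tad_end)
  p * cfg$boundary_factor^(-cross)
}

#' Generate a synthetic contact matrix and viewpoint profile
#'
#' Expected counts follow `count_scale * d^(-decay_exponent)` in bin
#' distance `d`, attenuated by `boundary_factor` per TAD boundary between
#' the two bins, and are Poisson-sampled. The viewpoint profile at the
#' promoter bin is extracted and converted to contact probabilities with
#' the anchor-adjacent rule, so it reproduces the intended decay within
#' sampling noise.
#'
#' @param cfg a [study_config()].
#' @param seed optional override of the substream seed.
#' @return List with `matrix` (a [contact_matrix()]), `profile` (counts
#'   scale) and `profile_prob` (probability scale).
#' @export
gen_contact_matrix <- function(cfg, seed = .substream_seeds(cfg$seed)[["matrix"]]) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  nb <- floor((cfg$region_end - cfg$region_start) / cfg$binsize)
  centers <- cfg$region_start + (seq_len(nb) - 0.5) * cfg$binsize
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  decay <- pmin(pmax(d, 0.5)^(-cfg$decay_exponent), 1)
  inside <- centers >= cfg$tad_start & centers <= cfg$tad_end
  left <- centers < cfg$tad_start
  side <- ifelse(left, -1L, ifelse(inside, 0L, 1L))
  cross <- abs(outer(side, side, "-"))  # boundaries crossed: 0, 1 or 2
  lambda <- cfg$count_scale * decay * cfg$boundary_factor^(-cross)
  up <- upper.tri(lambda, diag = TRUE)
  counts <- matrix(0, nb, nb)
  counts[up] <- stats::rpois(sum(up), lambda[up])
  counts <- counts + t(counts) - diag(diag(counts))
  cm <- contact_matrix(counts, cfg$chrom, cfg$region_start, cfg$binsize)
  vp <- viewpoint_profile(cm, cfg$promoter)
  list(matrix = cm, profile = vp,
       profile_prob = counts_to_probability(vp))
}

#' Generate insertion positions
#'
#' Positions are uniform within the TAD with probability
#' `inside_fraction`, otherwise uniform in the rest of the region;
#' orientation is random.
#'
#' @inheritParams gen_contact_matrix
#' @return data.frame `id`, `coord`, `orientation`, `inside_tad`.
#' @export
gen_insertions <- function(cfg,
                           seed = .substream_seeds(cfg$seed)[["insertions"]]) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  n <- cfg$n_lines
  inside <- stats::runif(n) < cfg$inside_fraction
  coord <- numeric(n)
  coord[inside] <- stats::runif(sum(inside), cfg$tad_start, cfg$tad_end)
  n_out <- sum(!inside)
  if (n_out > 0) {
    left_width <- cfg$tad_start - cfg$region_start
    total <- left_width + (cfg$region_end - cfg$tad_end)
    u <- stats::runif(n_out, 0, total)
    coord[!inside] <- ifelse(u < left_width, cfg$region_start + u,
                             cfg$tad_end + (u - left_width))
  }
  data.frame(id = sprintf("L%03d", seq_len(n)), coord = round(coord),
             orientation = sample(c("+", "-"), n, replace = TRUE),
             inside_tad = inside, stringsAsFactors = FALSE)
}

# ground-truth mean mRNA at contact probability p
.truth_mean <- function(cfg, p) {
  .model_mean(cfg$truth, p, cfg$model)
}

# ground-truth on rate at p (for sampling pmfs)
.truth_kon <- function(cfg, p) {
  .model_kon(cfg$truth, p, cfg$model)
}

#' Generate the screen expression table
#'
#' Each line's true mean is the ground-truth model mean at its contact
#' probability; `n_rep` replicate means are drawn with multiplicative
#' log-normal noise of the configured CV, and promoter-only control lines
#' are appended at `p_c = 0`.
#'
#' @inheritParams gen_contact_matrix
#' @param insertions insertion table from [gen_insertions()].
#' @param p_c per-insertion contact probabilities (defaults to the true
#'   decay curve at the insertion coordinates).
#' @return A [screen_dataset()] with the per-line replicate summary; the
#'   replicate draws are attached as attribute `replicates`.
#' @export
gen_screen <- function(cfg, insertions, p_c = .true_pc(cfg, insertions$coord),
                       seed = .substream_seeds(cfg$seed)[["screen"]]) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  ids <- c(insertions$id, sprintf("P%02d", seq_len(cfg$n_promoter_only)))
  coord <- c(insertions$coord, rep(NA, cfg$n_promoter_only))
  orient <- c(insertions$orientation, rep(NA, cfg$n_promoter_only))
  pc <- c(p_c, rep(0, cfg$n_promoter_only))
  true_mean <- .truth_mean(cfg, pc)
  n <- length(ids)
  if (cfg$replicate_cv > 0) {
    slog <- sqrt(log(1 + cfg$replicate_cv^2))
    noise <- matrix(stats::rlnorm(n * cfg$n_rep, -slog^2 / 2, slog), n)
  } else {
    noise <- matrix(1, n, cfg$n_rep)
  }
  reps <- true_mean * noise
  rep_sd <- if (n > 0) apply(reps, 1, stats::sd) else numeric(0)
  out <- data.frame(id = ids, coord = coord, orientation = orient,
                    p_c = pc, mean = rowMeans(reps),
                    sd = rep_sd,
                    n_rep = if (n > 0) cfg$n_rep else integer(0),
                    true_mean = true_mean,
                    stringsAsFactors = FALSE)
  out <- screen_dataset(out)
  attr(out, "replicates") <- reps
  out
}

#' Generate smFISH count data
#'
#' Chooses `n_fish` lines spanning the contact-probability range (the
#' lowest- and highest-p_c lines plus evenly spaced quantiles; one
#' promoter-only line is included when present) and samples each line's
#' per-cell counts from the ground-truth stationary mRNA distribution.
#'
#' @inheritParams gen_contact_matrix
#' @param screen a [screen_dataset()] (typically from [gen_screen()]).
#' @param lines optional character vector of line ids to use instead of
#'   the automatic spanning choice.
#' @return A [fish_dataset()].
#' @export
gen_fish <- function(cfg, screen, lines = NULL,
                     seed = .substream_seeds(cfg$seed)[["fish"]]) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(seed)
  if (is.null(lines)) {
    ord <- order(screen$p_c)
    qs <- unique(round(seq(1, length(ord), length.out = cfg$n_fish)))
    lines <- screen$id[ord[qs]]
  }
  idx <- match(lines, screen$id)
  if (any(is.na(idx))) stop("unknown line ids")
  pc <- screen$p_c[idx]
  cells <- lapply(pc, function(p) {
    kon <- .truth_kon(cfg, p)
    pmf <- .telegraph_pmf_core(kon, cfg$truth$k_off, cfg$truth$mu, 1, 1e-8)
    sample(seq_along(pmf) - 1L, cfg$cells_per_line, replace = TRUE,
           prob = pmf)
  })
  fish_dataset(lines, pc, cells = cells)
}

#' Generate a complete synthetic study
#'
#' Composes [gen_contact_matrix()], [gen_insertions()], [gen_screen()] and
#' [gen_fish()] under independent substreams of the study seed, and
#' optionally writes every component (plus the ground truth) to plain-text
#' files via [write_study()].
#'
#' @inheritParams gen_contact_matrix
#' @param outdir optional output directory.
#' @return Object of class `study_bundle`: `config`, `contacts` (matrix +
#'   profiles), `insertions`, `screen`, `fish`, `truth`, `seed`.
#' @export
gen_full_study <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  seeds <- .substream_seeds(cfg$seed)
  contacts <- gen_contact_matrix(cfg, seeds[["matrix"]])
  insertions <- gen_insertions(cfg, seeds[["insertions"]])
  screen <- gen_screen(cfg, insertions, seed = seeds[["screen"]])
  fish <- if (cfg$n_fish > 0 && nrow(screen) > 0)
    gen_fish(cfg, screen, seed = seeds[["fish"]]) else NULL
  bundle <- structure(list(config = cfg, contacts = contacts,
                           insertions = insertions, screen = screen,
                           fish = fish, truth = cfg$truth,
                           seed = cfg$seed, substreams = seeds),
                      class = "study_bundle")
  if (!is.null(outdir)) write_study(bundle, outdir)
  bundle
}

#' Write a study bundle to plain-text files
#'
#' Writes `screen.tsv`, `insertions.tsv`, `fish.csv` (long format: line,
#' cell, count), `contacts.tsv` (dense matrix with header),
#' `profile.bedGraph`, `tad.bed`, `promoter.bed` and `truth.json` (ground
#' truth, model and seed).
#'
#' @param bundle a [gen_full_study()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  utils::write.table(bundle$screen, file.path(outdir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$insertions,
                     file.path(outdir, "insertions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$fish)) {
    long <- do.call(rbind, lapply(seq_along(bundle$fish$id), function(i) {
      h <- bundle$fish$hist[[i]]
      counts <- rep(seq_along(h) - 1L, h)
      data.frame(line = bundle$fish$id[i], cell = seq_along(counts),
                 count = counts)
    }))
    utils::write.csv(long, file.path(outdir, "fish.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  write_contact_matrix(bundle$contacts$matrix,
                       file.path(outdir, "contacts.tsv"))
  write_profile_bedgraph(bundle$contacts$profile_prob,
                         file.path(outdir, "profile.bedGraph"))
  write_bed(data.frame(chrom = cfg$chrom, start = cfg$tad_start,
                       end = cfg$tad_end, name = "TAD"),
            file.path(outdir, "tad.bed"))
  write_bed(data.frame(chrom = cfg$chrom, start = cfg$promoter,
                       end = cfg$promoter + 1, name = "promoter"),
            file.path(outdir, "promoter.bed"))
  jsonlite::write_json(
    list(model = cfg$model, truth = cfg$truth, seed = cfg$seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Read a study bundle back from disk
#'
#' @param dir directory written by [write_study()].
#' @return List with `screen`, `insertions`, `fish`, `contacts`, `truth`.
#' @export
read_study <- function(dir) {
  screen <- screen_dataset(utils::read.delim(file.path(dir, "screen.tsv")))
  insertions <- utils::read.delim(file.path(dir, "insertions.tsv"))
  fish <- NULL
  fp <- file.path(dir, "fish.csv")
  if (file.exists(fp)) {
    long <- utils::read.csv(fp)
    pc <- stats::setNames(screen$p_c, screen$id)
    fish <- fish_from_table(long, pc)
  }
  contacts <- read_contact_matrix(file.path(dir, "contacts.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(screen = screen, insertions = insertions, fish = fish,
       contacts = contacts, truth = truth)
}
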