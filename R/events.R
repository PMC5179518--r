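#' Default optical model of the synthetic cytometer
#'
#' Marker fluorescence is a two-component log-normal mixture: a negative
#' (autofluorescence) component and a positive component roughly ten-fold
#' brighter, which produces the bimodal marker histograms characteristic of
#' stained samples. Scatter channels are Gaussian per population; the
#' proliferation dye starts at an undivided mean and halves per generation
#' with multiplicative log-normal spread.
#'
#' @return A list of optical parameters; override any element and pass to
#'   [simulate_events()].
#' @export
default_optics <- function() {
  list(
    neg_meanlog = log(100), neg_sdlog = 0.35,
    pos_meanlog = log(1000), pos_sdlog = 0.35,
    fsc_mean = 50000, fsc_sd = 4000,
    ssc_mean = 30000, ssc_sd = 4000,
    debris_fsc_mean = 8000, debris_fsc_sd = 2500,
    debris_ssc_mean = 6000, debris_ssc_sd = 2500,
    width_intercept = 20, width_slope = 8e-4, width_sd = 1.5,
    viability_live_meanlog = log(100), viability_live_sdlog = 0.35,
    viability_dead_meanlog = log(8000), viability_dead_sdlog = 0.35,
    dye_undivided_mean = 20000, dye_cv = 0.05
  )
}

#' Simulate a single-cell cytometry event table
#'
#' Generates one synthetic sample with full ground truth: lymphocyte events
#' with bimodal marker fluorescence (per-marker %positive, optional Gaussian
#' copula co-expression between markers), proliferation-dye dilution across
#' generations, and debris / doublet / dead-cell contamination. Marker
#' intensity is the mixture-quantile transform of the copula's uniform score,
#' so rank correlations between markers equal the copula's rank correlation.
#'
#' @param fraction_spec Named numeric vector: marker -> %positive (0-100).
#' @param n_cells Number of events (> 0).
#' @param copula Optional marker correlation matrix (latent Gaussian scale),
#'   dimnames matching `fraction_spec`; identity when `NULL`.
#' @param optics Optical model, see [default_optics()].
#' @param contamination Named numeric vector with elements `debris`,
#'   `doublet`, `dead` (fractions in \[0,1\), summing to < 1).
#' @param generations Numeric vector of generation weights (index 0 first);
#'   default: all cells undivided.
#' @param meta Named list recorded on the sample (e.g. donor, condition_id,
#'   time_days); stored as constant columns.
#' @param seed Integer seed.
#' @return A tibble with scatter, viability, proliferation-dye and marker
#'   channels, the `meta` columns, and ground-truth columns `truth_class`
#'   (lymphocyte/debris/doublet/dead), `truth_generation`, and
#'   `truth_pos_<marker>` flags.
#' @export
simulate_events <- function(fraction_spec,
                            n_cells,
                            copula = NULL,
                            optics = default_optics(),
                            contamination = c(debris = 0, doublet = 0, dead = 0),
                            generations = 1,
                            meta = list(),
                            seed = 1) {
  if (n_cells <= 0) abort("`n_cells` must be positive.")
  if (any(fraction_spec < 0 | fraction_spec > 100)) {
    abort("`fraction_spec` entries must be percentages in [0, 100].")
  }
  if (is.null(names(fraction_spec)) || anyDuplicated(names(fraction_spec))) {
    abort("`fraction_spec` must have unique marker names.")
  }
  cc <- c(debris = 0, doublet = 0, dead = 0)
  if (length(contamination)) {
    if (is.null(names(contamination)) ||
        !all(names(contamination) %in% names(cc))) {
      abort("`contamination` must be named among debris/doublet/dead.")
    }
    cc[names(contamination)] <- contamination
  }
  if (any(cc < 0) || sum(cc) >= 1) {
    abort("Contamination fractions must be nonnegative and sum to < 1.")
  }
  optics <- modifyList(default_optics(), optics)
  set.seed(derive_seed(seed, 1))

  markers <- names(fraction_spec)
  m <- length(markers)
  p <- fraction_spec / 100

  cls <- sample(c("lymphocyte", "debris", "doublet", "dead"), n_cells,
                replace = TRUE,
                prob = c(1 - sum(cc), cc[["debris"]], cc[["doublet"]],
                         cc[["dead"]]))

  # latent copula scores -> uniform -> mixture quantile
  if (is.null(copula)) copula <- diag(m)
  copula <- as.matrix(copula)
  if (!all(dim(copula) == m)) abort("`copula` must be markers x markers.")
  ch <- chol(copula)
  z <- matrix(rnorm(n_cells * m), n_cells, m) %*% ch
  u <- pnorm(z)
  colnames(u) <- markers

  intensity <- matrix(0, n_cells, m, dimnames = list(NULL, markers))
  pos <- matrix(FALSE, n_cells, m, dimnames = list(NULL, markers))
  for (j in seq_len(m)) {
    pj <- p[j]
    is_pos <- u[, j] >= 1 - pj
    pos[, j] <- is_pos
    v <- numeric(n_cells)
    if (any(!is_pos)) {
      v[!is_pos] <- qlnorm(u[!is_pos, j] / (1 - pj),
                           optics$neg_meanlog, optics$neg_sdlog)
    }
    if (any(is_pos)) {
      v[is_pos] <- qlnorm((u[is_pos, j] - (1 - pj)) / pj,
                          optics$pos_meanlog, optics$pos_sdlog)
    }
    intensity[, j] <- v
  }

  # proliferation generations
  gw <- generations / sum(generations)
  gen <- sample(seq_along(gw) - 1L, n_cells, replace = TRUE, prob = gw)
  dye_sdlog <- log1p(optics$dye_cv)
  dye <- optics$dye_undivided_mean / 2^gen *
    rlnorm(n_cells, -dye_sdlog^2 / 2, dye_sdlog)

  # scatter and viability by population class
  fsc <- rnorm(n_cells, optics$fsc_mean, optics$fsc_sd)
  ssc <- rnorm(n_cells, optics$ssc_mean, optics$ssc_sd)
  deb <- cls == "debris"
  fsc[deb] <- rnorm(sum(deb), optics$debris_fsc_mean, optics$debris_fsc_sd)
  ssc[deb] <- rnorm(sum(deb), optics$debris_ssc_mean, optics$debris_ssc_sd)
  dbl <- cls == "doublet"
  fsc[dbl] <- 2 * fsc[dbl]
  width <- optics$width_intercept + optics$width_slope * fsc +
    rnorm(n_cells, 0, optics$width_sd)
  width[dbl] <- 2 * width[dbl]
  intensity[dbl, ] <- 2 * intensity[dbl, ]

  viab <- rlnorm(n_cells, optics$viability_live_meanlog,
                 optics$viability_live_sdlog)
  dd <- cls == "dead"
  viab[dd] <- rlnorm(sum(dd), optics$viability_dead_meanlog,
                     optics$viability_dead_sdlog)

  out <- tibble(
    `FSC-A` = pmax(fsc, 1), `FSC-W` = pmax(width, 1), `SSC-A` = pmax(ssc, 1),
    Viability = viab, ProlifDye = dye
  )
  for (j in seq_len(m)) out[[markers[j]]] <- intensity[, j]
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out$truth_class <- cls
  out$truth_generation <- gen
  for (j in seq_len(m)) out[[paste0("truth_pos_", markers[j])]] <- pos[, j]
  attr(out, "seed") <- derive_seed(seed, 1)
  out
}

#' Channel columns of an event table
#'
#' Everything that is not ground truth (`truth_*`) or sample metadata
#' (`donor`, `condition_id`, `time_days`, `experiment`, `group`) is a channel.
#'
#' @param events Event tibble.
#' @return Character vector of channel names.
#' @export
channel_names <- function(events) {
  meta_cols <- c("donor", "condition_id", "time_days", "experiment", "group")
  setdiff(names(events), c(meta_cols, grep("^truth_", names(events),
                                           value = TRUE)))
}

#' Write / read an event table
#'
#' CSV is the canonical interchange: the first row holds channel names, one
#' event per row; sample metadata and ground-truth labels go to a JSON
#' sidecar (`<path>.meta.json`). A minimal FCS 3.1 writer/reader (list-mode,
#' 32-bit float data) is provided for interoperability; FCS carries channels
#' only.
#'
#' @param events Event tibble (see [simulate_events()]).
#' @param path Output path.
#' @param format `"csv"` or `"fcs"`.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an event tibble.
#' @export
write_events <- function(events, path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  chans <- channel_names(events)
  if (length(chans) == 0) abort("Event table has no channel columns.")
  if (anyDuplicated(chans)) abort("Channel names must be unique.")
  mat <- as.matrix(events[chans])
  if (any(mat < 0)) abort("Negative intensities are not a valid event table.")
  if (format == "csv") {
    write.csv(events[chans], path, row.names = FALSE)
    extra <- setdiff(names(events), chans)
    side <- list()
    meta_cols <- intersect(c("donor", "condition_id", "time_days",
                             "experiment", "group"), extra)
    if (length(meta_cols)) {
      side$sample_meta <- lapply(events[meta_cols], function(v) v[[1]])
    }
    truth_cols <- grep("^truth_", extra, value = TRUE)
    if (length(truth_cols)) side$truth <- as.list(events[truth_cols])
    if (length(side)) {
      jsonlite::write_json(side, paste0(path, ".meta.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    write_fcs(mat, path)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE)
    if (anyDuplicated(names(df))) abort("Duplicate channel names in CSV.")
    out <- as_tibble(df)
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      for (nm in names(side$sample_meta)) out[[nm]] <- side$sample_meta[[nm]]
      for (nm in names(side$truth)) out[[nm]] <- side$truth[[nm]]
    }
    out
  } else {
    read_fcs(path)
  }
}

# --- minimal FCS 3.1 (list mode, $DATATYPE=F) -------------------------------
# Header: "FCS3.1    " then six 8-char right-justified ASCII offsets
# (TEXT begin/end, DATA begin/end, ANALYSIS begin/end). TEXT is
# delimiter-framed key/value pairs; DATA is little-endian float32, one event
# after another, parameters in order.

write_fcs <- function(mat, path) {
  n <- nrow(mat); k <- ncol(mat)
  if (k == 0) abort("Event table has no channel columns.")
  delim <- "/"
  kw <- c("$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(k), "$TOT", as.character(n))
  for (j in seq_len(k)) {
    kw <- c(kw, paste0("$P", j, "N"), colnames(mat)[j],
            paste0("$P", j, "B"), "32", paste0("$P", j, "E"), "0,0",
            paste0("$P", j, "R"), "1048576")
  }
  pad8 <- function(x) formatC(x, width = 8, flag = "0")
  build_text <- function(db, de) {
    paste0(delim, paste(c(kw, "$BEGINDATA", pad8(db), "$ENDDATA", pad8(de)),
                        collapse = delim), delim)
  }
  text_start <- 58L
  txt <- build_text(0, 0)
  text_end <- text_start + nchar(txt) - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * k - 1L
  txt <- build_text(data_start, data_end)  # same width, offsets now real
  header <- paste0("FCS3.1    ",
                   formatC(text_start, width = 8), formatC(text_end, width = 8),
                   formatC(data_start, width = 8), formatC(data_end, width = 8),
                   formatC(0, width = 8), formatC(0, width = 8))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (substr(header, 1, 6) != "FCS3.1") abort("Not an FCS 3.1 file.")
  off <- as.integer(substring(header,
                              10 + 8 * (0:5) + 1, 10 + 8 * (1:6)))
  text_start <- off[1]; text_end <- off[2]
  seek(con, text_start)
  txt <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substr(txt, 2, nchar(txt) - 1), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 != 0) abort("Malformed FCS TEXT segment.")
  keys <- parts[seq(1, length(parts), 2)]
  vals <- parts[seq(2, length(parts), 2)]
  kv <- setNames(vals, keys)
  k <- as.integer(kv[["$PAR"]]); n <- as.integer(kv[["$TOT"]])
  data_start <- as.integer(kv[["$BEGINDATA"]] %||% off[3])
  chans <- vapply(seq_len(k), function(j) kv[[paste0("$P", j, "N")]], "")
  seek(con, data_start)
  vals <- readBin(con, "numeric", n * k, size = 4, endian = "little")
  mat <- matrix(vals, nrow = n, ncol = k, byrow = TRUE)
  colnames(mat) <- chans
  as_tibble(mat)
}
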