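#' Read an FSL-style gradient table
#'
#' Reads `bvec` (3 rows x N columns) and `bval` (1 row x N) whitespace-
#' separated text tables.  On-disk b-values are in s/mm^2 and are converted
#' to ms/um^2 (factor 1/1000).  Direction columns are unit-normalized;
#' zero vectors are only allowed where b = 0 (they are replaced by +z so
#' every stored direction is unit norm).  Shell ids are inferred by
#' clustering b-values within 5 percent relative tolerance; if any inferred
#' shell is not internally consistent the scheme is left non-shelled.
#'
#' @param bvec_path,bval_path file paths.
#' @param Delta,delta pulse timing, ms (not stored in FSL tables).
#' @return a [gradient_scheme()].
#' @export
read_gradient_table <- function(bvec_path, bval_path,
                                Delta = 43.1, delta = 10.6) {
  bvec <- parse_numeric_table(bvec_path, expect_rows = 3)
  bval <- parse_numeric_table(bval_path, expect_rows = 1)
  if (ncol(bvec) != ncol(bval)) {
    stop("bvec has ", ncol(bvec), " columns but bval has ", ncol(bval))
  }
  b <- as.numeric(bval[1, ]) / 1000   # s/mm^2 -> ms/um^2
  u <- t(bvec)
  nrm <- sqrt(rowSums(u^2))
  zero <- nrm < 1e-8
  if (any(zero & b > 1e-9)) {
    stop("zero direction vector at b > 0 (column ",
         which(zero & b > 1e-9)[1], ")")
  }
  u[zero, ] <- matrix(rep(c(0, 0, 1), sum(zero)), ncol = 3, byrow = TRUE)
  if (any(!zero & abs(nrm - 1) > 1e-6)) {
    warning("non-unit bvec columns normalized")
  }
  u <- u / sqrt(rowSums(u^2))
  shell_ids <- infer_shells(b)
  # only keep the shell structure if every cluster is exactly mono-b;
  # jittered (e.g. gradient-biased) tables stay non-shelled
  if (!is.null(shell_ids)) {
    for (s in setdiff(unique(shell_ids), 0L)) {
      if (diff(range(b[shell_ids == s])) > 1e-9) {
        shell_ids <- NULL
        break
      }
    }
  }
  gradient_scheme(u, b, shell_ids, Delta = Delta, delta = delta)
}

# cluster b-values within 5% relative tolerance; shell 0 reserved for b=0
infer_shells <- function(b, rel_tol = 0.05) {
  ids <- integer(length(b))
  centers <- numeric(0)
  for (i in order(b)) {
    if (b[i] == 0) { ids[i] <- 0L; next }
    hit <- which(abs(centers - b[i]) <= rel_tol * centers)
    if (length(hit) >= 1) {
      ids[i] <- hit[1]
    } else {
      centers <- c(centers, b[i])
      ids[i] <- length(centers)
    }
  }
  ids
}

parse_numeric_table <- function(path, expect_rows) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != expect_rows) {
    stop(path, ": expected ", expect_rows, " rows, found ", length(lines))
  }
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      stop(path, ": non-numeric token on line ", i, ": '",
           toks[which(is.na(vals))[1]], "'")
    }
    vals
  })
  if (length(unique(lengths(rows))) != 1) {
    stop(path, ": rows have differing lengths")
  }
  do.call(rbind, rows)
}

#' Write an FSL-style gradient table
#'
#' Inverse of [read_gradient_table()]: writes `bvec`/`bval` with b in
#' s/mm^2, at 9 significant digits so a round trip is faithful to printed
#' precision.
#'
#' @param scheme a [gradient_scheme()].
#' @param bvec_path,bval_path output paths.
#' @export
write_gradient_table <- function(scheme, bvec_path, bval_path) {
  u <- t(scheme$directions)
  fmt <- function(x) format(x, digits = 9, scientific = FALSE, trim = TRUE)
  writeLines(apply(u, 1, function(r) paste(fmt(r), collapse = " ")),
             bvec_path)
  writeLines(paste(fmt(scheme$b_values * 1000), collapse = " "), bval_path)
  invisible(NULL)
}

#' Write / read a scheme as CSV
#'
#' Columns (ux, uy, uz, b, shell_id); b in ms/um^2.  Timing is carried in
#' a header comment line.
#'
#' @param scheme a [gradient_scheme()].
#' @param path CSV path.
#' @export
write_scheme_csv <- function(scheme, path) {
  df <- data.frame(ux = scheme$directions[, 1], uy = scheme$directions[, 2],
                   uz = scheme$directions[, 3], b = scheme$b_values,
                   shell_id = if (is.null(scheme$shell_ids)) NA_integer_
                              else scheme$shell_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Delta=%.9g delta=%.9g", scheme$Delta, scheme$delta),
             con)
  utils::write.csv(format(df, digits = 12), con, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}

#' @rdname write_scheme_csv
#' @export
read_scheme_csv <- function(path) {
  first <- readLines(path, n = 1)
  timing <- c(Delta = 43.1, delta = 10.6)
  if (startsWith(first, "#")) {
    m <- regmatches(first,
                    gregexpr("=-?[0-9.]+([eE][-+]?[0-9]+)?", first))[[1]]
    m <- as.numeric(sub("=", "", m))
    timing <- c(Delta = m[1], delta = m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  shell_ids <- if (all(is.na(df$shell_id))) NULL else as.integer(df$shell_id)
  gradient_scheme(as.matrix(df[, c("ux", "uy", "uz")]), df$b, shell_ids,
                  Delta = unname(timing["Delta"]),
                  delta = unname(timing["delta"]))
}

#' Write / read signals with their scheme as a single CSV
#'
#' Columns (ux, uy, uz, b, shell_id, S).
#'
#' @param signals a `signal_array`.
#' @param path CSV path.
#' @export
write_signals_csv <- function(signals, path) {
  sch <- signals$scheme
  df <- data.frame(ux = sch$directions[, 1], uy = sch$directions[, 2],
                   uz = sch$directions[, 3], b = sch$b_values,
                   shell_id = if (is.null(sch$shell_ids)) NA_integer_
                              else sch$shell_ids,
                   S = signals$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Delta=%.9g delta=%.9g sigma=%.9g model=%s",
                     sch$Delta, sch$delta, signals$noise_sigma,
                     signals$noise_model), con)
  utils::write.csv(format(df, digits = 12), con, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}

#' @rdname write_signals_csv
#' @export
read_signals_csv <- function(path) {
  first <- readLines(path, n = 1)
  Delta <- 43.1; delta <- 10.6; sigma <- 0; nm <- "none"
  if (startsWith(first, "#")) {
    m <- regmatches(first,
                    gregexpr("=-?[0-9.]+([eE][-+]?[0-9]+)?", first))[[1]]
    m <- as.numeric(sub("=", "", m))
    Delta <- m[1]; delta <- m[2]; sigma <- m[3]
    nm <- sub(".*model=", "", first)
  }
  df <- utils::read.csv(path, comment.char = "#")
  shell_ids <- if (all(is.na(df$shell_id))) NULL else as.integer(df$shell_id)
  sch <- gradient_scheme(as.matrix(df[, c("ux", "uy", "uz")]), df$b,
                         shell_ids, Delta = Delta, delta = delta)
  signal_array(df$S, sch, noise_sigma = sigma, noise_model = nm)
}

#' Write a powder average as CSV
#'
#' @param pa a `powder_average`.
#' @param path CSV path.
#' @export
write_powder_average_csv <- function(pa, path) {
  utils::write.csv(data.frame(b = pa$b_values, s_bar = pa$s_bar,
                              method = pa$method_tag),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Generate the study's synthetic fixture tree
#'
#' Writes every point set of the study (488 = 61 x 8 shelled uniform,
#' 344 = 43 x 8 and 152 = 19 x 8 shelled Lebedev, their non-shelled
#' counterparts, and the two random 344 variants), noise-free signals for
#' kappa in \{1, 9, Inf\} plus the two crossing configurations, and one
#' noisy realization per noise level on the 344 shelled scheme, with a
#' JSON manifest recording seeds and file hashes.
#'
#' @param out_dir output directory (created if needed).
#' @param master_seed integer seed.
#' @param sigma_list noise levels for the noisy realizations.
#' @return (invisibly) the manifest list.
#' @export
generate_fixtures <- function(out_dir, master_seed = 1L,
                              sigma_list = c(0.1414, 0.0707, 0.0283,
                                             0.0071, 0.0014)) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("unwritable path: ", out_dir)
  b_shells <- seq(1.5, 12, by = 1.5)
  schemes <- list(
    shelled_488    = build_scheme("shelled_uniform", 61, b_shells,
                                  seed = master_seed),
    shelled_344    = build_scheme("shelled_lebedev", 43, b_shells),
    shelled_152    = build_scheme("shelled_lebedev", 19, b_shells),
    shelled_344_random = build_scheme("shelled_random", 43, b_shells,
                                      seed = master_seed),
    nonshelled_488 = build_scheme("nonshelled", 488, b_max = 12,
                                  seed = master_seed),
    nonshelled_344 = build_scheme("nonshelled", 344, b_max = 12,
                                  seed = master_seed),
    nonshelled_152 = build_scheme("nonshelled", 152, b_max = 12,
                                  seed = master_seed),
    nonshelled_344_random = build_scheme("nonshelled_random", 344,
                                         b_max = 12, seed = master_seed)
  )
  manifest <- list(package_version = as.character(
                     utils::packageVersion("powderavg")),
                   master_seed = master_seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   files = list())
  for (nm in names(schemes)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_scheme_csv(schemes[[nm]], p)
    manifest$files[[basename(p)]] <- unname(tools::md5sum(p))
  }
  # noise-free signals on the 344 shelled scheme
  sch <- schemes$shelled_344
  models <- list(kappa1 = tissue_model(kappa = 1),
                 kappa9 = tissue_model(kappa = 9),
                 kappaInf = tissue_model(kappa = Inf),
                 crossing_pi2 = crossing_model("pi/2", kappa = Inf),
                 crossing_pi4 = crossing_model("pi/4", kappa = Inf))
  for (nm in names(models)) {
    sig <- simulate_signal(sch, models[[nm]])
    p <- file.path(out_dir, paste0("signal_344_", nm, ".csv"))
    write_signals_csv(sig, p)
    manifest$files[[basename(p)]] <- unname(tools::md5sum(p))
  }
  # one noisy realization per sigma level (kappa = Inf, Gaussian)
  base <- simulate_signal(sch, models$kappaInf)
  for (si in seq_along(sigma_list)) {
    noisy <- add_noise(base, sigma_list[si], model = "gaussian",
                       seed = master_seed + si)
    p <- file.path(out_dir,
                   sprintf("signal_344_kappaInf_sigma%g.csv", sigma_list[si]))
    write_signals_csv(noisy, p)
    manifest$files[[basename(p)]] <- unname(tools::md5sum(p))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run manifest for a command-line invocation
#'
#' @param config_path optional config file whose md5 is recorded.
#' @param master_seed integer seed.
#' @param inputs,outputs character vectors of paths.
#' @return list with version, config hash, seed, timestamp and paths.
#' @export
run_manifest <- function(config_path = NULL, master_seed = NA_integer_,
                         inputs = character(), outputs = character()) {
  list(tool = "powderavg",
       version = as.character(utils::packageVersion("powderavg")),
       config_md5 = if (is.null(config_path)) NA_character_
                    else unname(tools::md5sum(config_path)),
       master_seed = master_seed,
       timestamp = format(Sys.time(), tz = "UTC"),
       inputs = inputs, outputs = outputs)
}
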