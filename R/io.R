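# Tab-delimited peak-table formats ('#'-comment lines, header row),
# validation with line-number diagnostics, and deterministic report output
# with provenance (config hash + seed).

.SCHEMAS <- list(
  decay = list(
    cols = c(residue = "integer", experiment = "character",
             delay_s = "numeric", intensity = "numeric", sigma = "numeric"),
    required = c("residue", "delay_s", "intensity"),
    key = c("residue", "experiment", "delay_s")
  ),
  noe = list(
    cols = c(residue = "integer", i_sat = "numeric", i_ref = "numeric",
             sigma_sat = "numeric", sigma_ref = "numeric"),
    required = c("residue", "i_sat", "i_ref"),
    key = "residue"
  ),
  cpmg = list(
    cols = c(residue = "integer", field_mhz = "numeric",
             nu_cpmg_hz = "numeric", intensity = "numeric",
             replicate = "integer"),
    required = c("residue", "field_mhz", "nu_cpmg_hz", "intensity"),
    key = c("residue", "field_mhz", "nu_cpmg_hz", "replicate")
  ),
  shift = list(
    cols = c(residue = "integer", ph = "numeric", dh_ppm = "numeric",
             dn_ppm = "numeric", status = "character", peakset = "character"),
    required = c("residue", "ph"),
    key = c("residue", "ph", "peakset")
  ),
  rates = list(
    cols = c(residue = "integer", ph = "numeric", field_mhz = "numeric",
             peakset = "character", r1 = "numeric", r1_sigma = "numeric",
             r2 = "numeric", r2_sigma = "numeric", noe = "numeric",
             noe_sigma = "numeric", r2_r1 = "numeric", r2_r1_sigma = "numeric"),
    required = c("residue", "r1", "r2", "noe"),
    key = c("residue", "ph", "field_mhz", "peakset")
  ),
  dispersion = list(
    cols = c(residue = "integer", field_mhz = "numeric",
             nu_cpmg_hz = "numeric", r2eff = "numeric",
             r2eff_sigma = "numeric", i0 = "numeric"),
    required = c("residue", "field_mhz", "nu_cpmg_hz", "r2eff"),
    key = c("residue", "field_mhz", "nu_cpmg_hz")
  ),
  modelfree = list(
    cols = c(residue = "integer", model = "character", status = "character",
             s2 = "numeric", s2_sigma = "numeric", tau_e = "numeric",
             tau_e_sigma = "numeric", s2f = "numeric", s2f_sigma = "numeric",
             rex = "numeric", rex_sigma = "numeric", chisq = "numeric"),
    required = c("residue", "model"),
    key = "residue"
  )
)

#' Read a validated peak table
#'
#' Reads one of the package's tab-delimited table formats. Lines starting
#' with `#` are comments; the first non-comment line is the header, which
#' must contain the schema's required columns (extra columns are kept as
#' character). Malformed rows are rejected with their line numbers;
#' duplicate keys are an error naming the offending line.
#'
#' @param path File path.
#' @param schema One of `"decay"`, `"noe"`, `"cpmg"`, `"shift"`,
#'   `"rates"`, `"dispersion"`, `"modelfree"`.
#' @return A typed tibble (possibly empty).
#' @export
read_peak_table <- function(path, schema) {
  if (!schema %in% names(.SCHEMAS))
    abort(sprintf("unknown schema '%s'.", schema))
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sc <- .SCHEMAS[[schema]]

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) abort("no header line found.")
  idx <- which(keep)
  header <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(sc$required, header)
  if (length(missing_cols))
    abort(sprintf("header lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))

  data_idx <- idx[-1]
  if (length(data_idx) == 0) {
    out <- lapply(sc$cols[names(sc$cols) %in% header], function(ty)
      vector(mode = switch(ty, integer = "integer", numeric = "double",
                           character = "character")))
    return(as_tibble(out))
  }

  cells <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    abort(sprintf("malformed row(s) at line(s) %s: wrong field count.",
                  paste(data_idx[bad], collapse = ", ")))
  mat <- do.call(rbind, cells)
  colnames(mat) <- header
  df <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))

  for (cn in intersect(names(sc$cols), header)) {
    ty <- sc$cols[[cn]]
    raw <- df[[cn]]
    if (ty %in% c("numeric", "integer")) {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !(raw %in% c("NA", "", "nan")))
      if (length(bad))
        abort(sprintf("non-numeric value in column '%s' at line(s) %s.",
                      cn, paste(data_idx[bad], collapse = ", ")))
      df[[cn]] <- if (ty == "integer") as.integer(round(val)) else val
    }
  }

  key <- intersect(sc$key, header)
  if (length(key)) {
    kd <- do.call(paste, c(df[key], sep = "\r"))
    dup <- which(duplicated(kd))
    if (length(dup))
      abort(sprintf("duplicate key (%s) at line %d.",
                    paste(key, collapse = ", "), data_idx[dup[1]]))
  }
  df
}

#' Write a peak table
#'
#' Deterministic tab-delimited output: fixed column order (schema columns
#' first), fixed decimal formatting, and optional `#` provenance header
#' lines (config hash and seed). Writing the same content twice produces
#' byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param schema Optional schema name for column ordering.
#' @param digits Decimal places for numeric columns.
#' @param comments Character vector of comment lines (without the `#`).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path, schema = NULL, digits = 6,
                             comments = character()) {
  stopifnot(is.data.frame(x))
  if (!is.null(schema)) {
    if (!schema %in% names(.SCHEMAS)) abort(sprintf("unknown schema '%s'.", schema))
    first <- intersect(names(.SCHEMAS[[schema]]$cols), names(x))
    x <- x[, c(first, setdiff(names(x), first)), drop = FALSE]
  }
  data_lines <- if (nrow(x) == 0) character() else {
    fmt <- lapply(x, function(col) {
      if (is.double(col)) trimws(formatC(col, digits = digits, format = "g"))
      else as.character(col)
    })
    do.call(paste, c(fmt, sep = "\t"))
  }
  con <- file(path, open = "wb")  # binary mode: identical newlines everywhere
  on.exit(close(con))
  writeLines(c(if (length(comments)) paste0("# ", comments),
               paste(names(x), collapse = "\t"),
               data_lines),
             con, sep = "\n")
  invisible(path)
}

#' Write an analysis report
#'
#' Writes the tidy table of a fitted object (or a plain data frame) as a
#' deterministic TSV with provenance comments: the package format version,
#' a hash of the configuration, and the seed. Skipped residues keep their
#' skip status. Same results in, byte-identical file out.
#'
#' @param results A `model_free_fit`, `dispersion_fit`, `diffusion_fit`
#'   or data frame.
#' @param path Output path.
#' @param seed Seed to record (taken from the object if present).
#' @param config A list of run options to hash into the provenance header.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, config = list()) {
  tbl <- if (is.data.frame(results)) as_tibble(results) else tidy(results)
  seed <- seed %||% (if (!is.data.frame(results)) results$seed else NULL)
  head_lines <- c(
    "relaxfit report v1",
    sprintf("config_hash: %s", hash(config)),
    sprintf("seed: %s", seed %||% "NA")
  )
  if (!is.data.frame(results) && inherits(results, "dispersion_fit")) {
    head_lines <- c(head_lines,
      sprintf("kex: %.6g", results$kex),
      sprintf("kex_sigma: %.6g", results$kex_sigma %||% NA),
      sprintf("papb: %.6g", results$papb),
      sprintf("papb_sigma: %.6g", results$papb_sigma %||% NA),
      sprintf("pa_percent: %.4f", 100 * results$pa))
  }
  if (!is.data.frame(results) && inherits(results, "diffusion_fit")) {
    head_lines <- c(head_lines,
      sprintf("tensor: %s", results$tensor$kind),
      sprintf("tau_m_ns: %.6g", results$tensor$tau_m),
      sprintf("d_ratio: %.6g", results$tensor$d_ratio))
  }
  write_peak_table(tbl, path, digits = 6, comments = head_lines)
}

#' Run configuration with defaults
#'
#' Collects every tunable of the pipeline — spin constants, field list,
#' design grids, fitting options, seed — with its default, as a plain
#' list that serialises losslessly to YAML. Unknown option names are
#' rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `run_config`.
#' @examples
#' run_config(seed = 7, alpha = 0.01)$alpha
#' @export
run_config <- function(...) {
  defaults <- list(
    field_mhz = c(800.2, 600.13),
    gamma_ratio = -9.8655,
    r_nh = 1.02,
    csa_ppm = -160,
    delays_r1 = .DEFAULT_R1_DELAYS,
    delays_r2 = .DEFAULT_R2_DELAYS,
    t_relax = 0.060,
    nu_cpmg = c(0, 50, 100, 100, 150, 200, 250, 300, 350, 400, 450, 500,
                600, 750),
    alpha = 0.05,
    criterion = "ftest",
    n_mc = 500,
    noe_min = 0.65,
    iqr_mult = 1.5,
    kex_grid = .DEFAULT_KEX_GRID,
    papb_grid = .DEFAULT_PAPB_GRID,
    csp_weight = 0.2,
    sigma_floor = 0.005,
    noise = 0.02,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    abort(paste("unknown config option(s):", paste(bad, collapse = ", ")))
  structure(modifyList(defaults, over), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path (YAML).
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the yaml package is required for config serialisation.")
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort("the yaml package is required for config serialisation.")
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
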