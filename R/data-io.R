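#' Read a solubility table from CSV
#'
#' Reads tabular saturation-solubility records. The expected header columns
#' are `solute, solvent1, solvent2, x2_star, temp, x` with optional
#' `temp_unit, u_x, source`. `solvent1` is the organic component (or the only
#' solvent); `solvent2` is the aqueous component of a binary and may be empty
#' for neat solvents; `x2_star` is the solute-free mole fraction of
#' `solvent1` in the mixed solvent; `x` is the mole-fraction solubility.
#'
#' Temperatures may be given in Kelvin or degrees Celsius: a per-row
#' `temp_unit` column (`"K"` or `"C"`) wins, otherwise the `temp_unit`
#' argument applies to the whole file. All temperatures are stored in Kelvin.
#'
#' Rows violating the record invariants (`x2_star` outside [0, 1], `x`
#' outside (0, 1], non-positive temperature, unparseable numbers) are dropped
#' with a per-row message; duplicated
#' (solute, solvent1, solvent2, x2_star, temperature, source) keys are kept
#' but flagged with a warning so the curation step can arbitrate.
#'
#' @param path Path to a CSV file.
#' @param temp_unit Default temperature unit when the file has no
#'   `temp_unit` column: `"K"` (default) or `"C"`.
#' @return A tibble with columns `solute, solvent1, solvent2, x2_star,
#'   temperature, x_solute, u_x, source` (temperature in K).
#' @seealso [write_solubility_table()], [table1_solubility()]
#' @export
read_solubility_table <- function(path, temp_unit = c("K", "C")) {
  temp_unit <- match.arg(temp_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("solute", "solvent1", "x2_star", "temp", "x")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  opt <- function(col, default) if (col %in% names(raw)) raw[[col]] else rep(default, n)

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(v))
    if (length(bad) > 0) {
      message("non-numeric `", col, "` in row(s) ", paste(bad, collapse = ", "),
              "; row(s) rejected")
    }
    list(value = v, bad = bad)
  }
  x2 <- num("x2_star"); tp <- num("temp"); xs <- num("x")
  u_raw <- if ("u_x" %in% names(raw)) suppressWarnings(as.numeric(raw$u_x)) else rep(NA_real_, n)

  unit <- toupper(trimws(opt("temp_unit", temp_unit)))
  unit[is.na(unit) | unit == ""] <- temp_unit
  temperature <- ifelse(unit == "C", tp$value + 273.15, tp$value)

  out <- tibble::tibble(
    solute   = as.character(raw$solute),
    solvent1 = as.character(raw$solvent1),
    solvent2 = as.character(opt("solvent2", NA_character_)),
    x2_star  = x2$value,
    temperature = temperature,
    x_solute = xs$value,
    u_x      = u_raw,
    source   = as.character(opt("source", "literature"))
  )
  out$solvent2[!is.na(out$solvent2) & out$solvent2 == ""] <- NA_character_

  reject <- rep(FALSE, n)
  mark <- function(idx, why) {
    idx <- setdiff(idx, which(reject))
    if (length(idx) > 0) {
      message("rejected row(s) ", paste(idx, collapse = ", "), ": ", why)
      reject[idx] <<- TRUE
    }
    invisible(NULL)
  }
  mark(unique(c(x2$bad, tp$bad, xs$bad)), "non-numeric field")
  mark(which(is.na(out$x2_star) | out$x2_star < 0 | out$x2_star > 1),
       "x2_star outside [0, 1]")
  mark(which(is.na(out$temperature) | out$temperature <= 0),
       "non-positive temperature")
  mark(which(is.na(out$x_solute) | out$x_solute <= 0 | out$x_solute > 1),
       "mole-fraction solubility outside (0, 1]")

  out <- out[!reject, , drop = FALSE]
  key <- paste(out$solute, out$solvent1, out$solvent2, out$x2_star,
               out$temperature, out$source, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicated record key(s) kept; ",
            "curation decides retention.", call. = FALSE)
  }
  out
}

#' Write a solubility table to CSV
#'
#' Emits the standard column layout read back by [read_solubility_table()];
#' temperatures are written in Kelvin with an explicit `temp_unit` column, so
#' a write/read round trip preserves every field.
#'
#' @param data A solubility tibble as returned by [read_solubility_table()].
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_solubility_table <- function(data, path) {
  out <- tibble::tibble(
    solute = data$solute, solvent1 = data$solvent1, solvent2 = data$solvent2,
    x2_star = data$x2_star, temp = data$temperature, temp_unit = "K",
    x = data$x_solute, u_x = data$u_x, source = data$source
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(data)
}

#' Read a solvent metadata table with environmental indices
#'
#' The environmental index (EI) is a scalar hazard score for a solvent
#' (lower is greener), consumed here as user-supplied metadata. A solvent is
#' classified green when its EI is strictly below `ei_threshold`
#' (default 0.5).
#'
#' @param path CSV with columns `solvent_id, ei` and optional `notes`.
#' @param ei_threshold Strict upper bound on EI for the green class.
#' @return A tibble `solvent_id, ei, green, notes`.
#' @export
read_solvent_meta <- function(path, ei_threshold = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("solvent_id", "ei") %in% names(raw))) {
    stop("solvent metadata needs columns `solvent_id` and `ei`.", call. = FALSE)
  }
  tibble::tibble(
    solvent_id = as.character(raw$solvent_id),
    ei = suppressWarnings(as.numeric(raw$ei)),
    green = suppressWarnings(as.numeric(raw$ei)) < ei_threshold,
    notes = if ("notes" %in% names(raw)) as.character(raw$notes) else NA_character_
  )
}

#' Measured solubility of acetaminophen and phenacetin in aqueous binaries
#'
#' The experimental mole-fraction solubility of acetaminophen (A) in aqueous
#' binary mixtures of DMSO, DMF and 4-formylmorpholine (4FM), and of
#' phenacetin (P) in aqueous 4FM, at 25-40 degrees C in 5-degree steps, as a
#' tidy record table (84 rows). The neat-water point is reported only for the
#' DMSO series (`x2_star = 0`). Values are plain mole fractions with their
#' reported uncertainties.
#'
#' @return A solubility tibble (see [read_solubility_table()]).
#' @examples
#' t1 <- table1_solubility()
#' dplyr::filter(t1, solvent1 == "DMSO", temperature == 298.15)
#' @export
table1_solubility <- function() {
  path <- system.file("extdata", "binary_solubility.csv", package = "cosolve")
  read_solubility_table(path)
}
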