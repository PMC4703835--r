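#' Variant classification vocabulary
#'
#' The canonical variant-class levels used throughout the package, and the
#' mapping from Mutation Annotation Format (MAF) dialect tokens onto them.
#' Tokens are matched case-insensitively; unrecognised tokens map to `"other"`
#' with a warning rather than an error, because real variant inventories
#' include classes (UTR, intronic, RNA, ...) outside the analysis set.
#'
#' @return `variant_classes()` returns the character vector of canonical
#'   levels.
#' @export
variant_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift_indel",
    "inframe_indel", "nonstop", "silent", "other")
}

# MAF dialect token -> canonical class (keys stored lower-case)
.maf_class_map <- c(
  "missense"           = "missense",
  "missense_mutation"  = "missense",
  "nonsense"           = "nonsense",
  "nonsense_mutation"  = "nonsense",
  "splice_site"        = "splice_site",
  "frame_shift_del"    = "frameshift_indel",
  "frame_shift_ins"    = "frameshift_indel",
  "frameshift_indel"   = "frameshift_indel",
  "in_frame_del"       = "inframe_indel",
  "in_frame_ins"       = "inframe_indel",
  "inframe_indel"      = "inframe_indel",
  "nonstop"            = "nonstop",
  "nonstop_mutation"   = "nonstop",
  "silent"             = "silent",
  "synonymous"         = "silent",
  "other"              = "other"
)

#' Normalise variant-class tokens
#'
#' @param x Character vector of MAF-dialect class tokens.
#' @return Character vector over the canonical levels of [variant_classes()].
#' @export
normalize_variant_class <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(.maf_class_map[key])
  unknown <- !is.na(key) & is.na(out)
  if (any(unknown)) {
    warn(paste0("Unrecognised variant_class token(s) mapped to 'other': ",
                paste(unique(x[unknown]), collapse = ", ")))
    out[unknown] <- "other"
  }
  out
}

.germline_cols <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                    "variant_class", "protein_pos", "maf_1000g", "maf_esp",
                    "n_ref", "n_alt", "t_ref", "t_alt")
.somatic_cols <- c("sample_id", "gene", "protein_pos", "variant_class",
                   "t_ref", "t_alt")

#' Read a germline or somatic variant table
#'
#' Reads the tab-delimited MAF-like dialect used throughout the package.
#' Germline tables carry per-sample calls with normal (`n_ref`, `n_alt`) and,
#' for tumour-bearing cases, tumour (`t_ref`, `t_alt`) read counts; controls
#' may leave the tumour counts empty. Somatic tables carry tumour counts only.
#' Coordinates are 1-based inclusive (MAF convention).
#'
#' @param path Path to a TSV file with a header row.
#' @param role `"germline"` or `"somatic"`; selects the required columns and
#'   validation rules.
#' @return A tibble with one row per data row. Rows violating an invariant
#'   (negative read counts, non-positive position, zero normal depth for a
#'   germline record) raise an error naming the offending data row.
#' @export
read_variant_table <- function(path, role = c("germline", "somatic")) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  req <- if (role == "germline") .germline_cols else .somatic_cols
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[req]
  num_cols <- intersect(
    c("pos", "protein_pos", "maf_1000g", "maf_esp",
      "n_ref", "n_alt", "t_ref", "t_alt"),
    names(df)
  )
  df <- df %>%
    mutate(across(dplyr::all_of(num_cols), as.numeric)) %>%
    mutate(variant_class = normalize_variant_class(.data$variant_class))
  int_cols <- intersect(c("pos", "protein_pos", "n_ref", "n_alt", "t_ref", "t_alt"),
                        names(df))
  validate_variant_table(df, role = role)
  df %>% mutate(across(dplyr::all_of(int_cols), as.integer)) %>% as_tibble()
}

#' Validate a variant tibble against the shared invariants
#'
#' @param df Tibble in the layout of [read_variant_table()].
#' @param role `"germline"` or `"somatic"`.
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending data row.
#' @export
validate_variant_table <- function(df, role = c("germline", "somatic")) {
  role <- match.arg(role)
  bad_row <- function(ok, what) {
    idx <- which(!ok)
    if (length(idx) > 0) {
      abort(paste0("Invalid ", role, " record at data row ", idx[1], ": ", what))
    }
  }
  count_cols <- if (role == "germline") c("n_ref", "n_alt", "t_ref", "t_alt")
                else c("t_ref", "t_alt")
  for (cc in intersect(count_cols, names(df))) {
    bad_row(is.na(df[[cc]]) | df[[cc]] >= 0, paste0("negative ", cc))
  }
  if ("pos" %in% names(df)) {
    bad_row(is.na(df$pos) | df$pos >= 1, "pos must be >= 1")
  }
  if (role == "germline") {
    bad_row(!is.na(df$n_ref) & !is.na(df$n_alt) & (df$n_ref + df$n_alt) > 0,
            "normal depth (n_ref + n_alt) must be > 0")
  } else {
    bad_row(!is.na(df$t_ref) & !is.na(df$t_alt) & (df$t_ref + df$t_alt) > 0,
            "tumour depth (t_ref + t_alt) must be > 0")
  }
  invisible(df)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id, role, cancer_type, age, sex,
#'   ethnicity`. `role` is `"case"` or `"control"`; cases must carry a
#'   `cancer_type`, controls must not (a populated control cancer_type is
#'   dropped with a warning).
#' @return Tibble with one row per sample; `sample_id` is unique.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  req <- c("sample_id", "role", "cancer_type", "age", "sex", "ethnicity")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df[req] %>% mutate(age = as.numeric(.data$age))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated sample_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (!all(df$role %in% c("case", "control"))) {
    abort("role must be 'case' or 'control'")
  }
  no_type <- is.na(df$cancer_type) | df$cancer_type == ""
  if (any(df$role == "case" & no_type)) {
    abort("case records must carry a cancer_type")
  }
  ctrl_typed <- df$role == "control" & !no_type
  if (any(ctrl_typed)) {
    warn("cancer_type set on control sample(s); field dropped")
    df$cancer_type[ctrl_typed] <- NA_character_
  }
  df$cancer_type[no_type] <- NA_character_
  as_tibble(df)
}

#' Read protein domain annotations
#'
#' @param path TSV with columns `protein, length, domain, start, end`; one row
#'   per domain, 1-based inclusive coordinates validated against the protein
#'   length.
#' @return A nested tibble with one row per protein: `protein`, `length`, and
#'   a `domains` list-column of tibbles (`domain`, `start`, `end`).
#' @export
read_domain_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  req <- c("protein", "length", "domain", "start", "end")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  df <- df %>% mutate(across(c("length", "start", "end"), as.integer))
  bad <- which(df$start < 1 | df$end < df$start | df$end > df$length)
  if (length(bad) > 0) {
    abort(paste0("Invalid domain interval at data row ", bad[1],
                 " (need 1 <= start <= end <= length)"))
  }
  df %>%
    tidyr::nest(domains = c("domain", "start", "end")) %>%
    select("protein", "length", "domains")
}

#' Write a results table
#'
#' Serialises any homogeneous result tibble as TSV with a deterministic column
#' order (the tibble's own order) and fixed-precision floats, so that
#' write -> read -> write round-trips byte-identically.
#'
#' @param df A tibble of results.
#' @param path Output path.
#' @param digits Significant digits for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path, digits = 10) {
  out <- df %>%
    mutate(across(dplyr::where(is.double),
                  ~ ifelse(is.na(.x), NA_character_,
                           sprintf(paste0("%.", digits, "g"), .x))))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by the reader.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  na = "NA")
}
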