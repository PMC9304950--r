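#' Write a cohort (and its truth sidecar) as CSV
#'
#' Wide dialect: header `family_id, twin, zygosity, sex, age,
#' <measure>_t<wave>..., gps_*`; missing cells are empty. The truth sidecar
#' (latent factor scores, class labels) is written to a separate file only
#' when a path is given, keeping it out of the analysis-facing table.
#'
#' @param cohort Cohort table.
#' @param path Output CSV path.
#' @param truth_path Optional sidecar CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- attr(cohort, "truth")
    if (is.null(truth)) warning("cohort has no truth sidecar; none written")
    else write.csv(truth, truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads the wide dialect written by [write_cohort()] and enforces the twin
#' structure: unique (family_id, twin) keys, exactly two rows per family,
#' zygosity codes MZ/DZ consistent within family, and matching sex for MZ
#' co-twins. Violations are hard errors listing the offending families.
#'
#' @param path CSV path.
#' @return The validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  req <- c("family_id", "twin", "zygosity", "sex", "age")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))

  key <- paste(d$family_id, d$twin)
  if (anyDuplicated(key))
    stop("duplicate (family_id, twin) row(s): ",
         paste(unique(key[duplicated(key)])[1:min(5, sum(duplicated(key)))],
               collapse = "; "))
  cnt <- table(d$family_id)
  bad_n <- names(cnt)[cnt != 2]
  if (length(bad_n))
    stop("families without exactly 2 rows: ",
         paste(head(bad_n, 5), collapse = ", "))
  bad_z <- unique(d$zygosity[!d$zygosity %in% c("MZ", "DZ")])
  if (length(bad_z))
    stop("unknown zygosity code(s): ", paste(bad_z, collapse = ", "))
  zyg_n <- tapply(d$zygosity, d$family_id, function(z) length(unique(z)))
  bad_zf <- names(zyg_n)[zyg_n > 1]
  if (length(bad_zf))
    stop("families with two zygosities: ",
         paste(head(bad_zf, 5), collapse = ", "))
  mz <- d[d$zygosity == "MZ", ]
  sex_n <- tapply(mz$sex, mz$family_id,
                  function(s) length(unique(s[!is.na(s)])))
  bad_s <- names(sex_n)[sex_n > 1]
  if (length(bad_s))
    stop("MZ families with mismatched sex: ",
         paste(head(bad_s, 5), collapse = ", "))

  pcols <- grep("_t[0-9]+$", names(d), value = TRUE)
  attr(d, "measures") <- unique(sub("_t[0-9]+$", "", pcols))
  attr(d, "n_waves") <- if (length(pcols))
    max(as.integer(sub(".*_t", "", pcols))) else 0L
  d
}
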