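#' Default analysis configuration
#'
#' Flat key-value list of every tunable threshold used across the pipeline.
#' Each value can be overridden by [read_config()] or per-call arguments.
#'
#' @return Named list of configuration values:
#' \describe{
#'   \item{window_width, window_step}{sliding-window geometry for locus scans
#'     (bp); defaults 1000 / 300.}
#'   \item{genome_window_width, genome_window_step}{geometry used for
#'     genome-background window distributions (bp); defaults 1e5 / 1e4.}
#'   \item{min_sites}{minimum informative sites for a window statistic.}
#'   \item{min_cov}{minimum read depth for a per-CpG methylation level.}
#'   \item{min_cov_allele}{minimum per-allele depth for a CpG to enter an
#'     allele-specific methylation track.}
#'   \item{dms_min_cov, dms_alpha}{coverage gate and significance level for
#'     differential-methylation-site calling.}
#'   \item{asm_window_cpgs, asm_fold_min, asm_diff_min, asm_alpha}{the ASM
#'     window procedure: 5 consecutive CpGs, fold change >= 2, absolute
#'     level difference >= 0.3, region t-test at alpha = 0.05.}
#'   \item{conversion_warn_below}{bisulfite conversion-rate warning
#'     threshold (0.98).}
#'   \item{z_side}{default sidedness of the window outlier Z-test.}
#' }
#' @export
default_config <- function() {
  list(
    window_width          = 1000L,
    window_step           = 300L,
    genome_window_width   = 100000L,
    genome_window_step    = 10000L,
    min_sites             = 1L,
    min_cov               = 5L,
    min_cov_allele        = 5L,
    dms_min_cov           = 10L,
    dms_alpha             = 0.05,
    asm_window_cpgs       = 5L,
    asm_fold_min          = 2.0,
    asm_diff_min          = 0.3,
    asm_alpha             = 0.05,
    conversion_warn_below = 0.98,
    z_side                = "greater"
  )
}

#' Read a configuration file
#'
#' Reads a flat YAML key-value file and merges it over [default_config()].
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path path to a YAML file of scalar keys.
#' @return Named list as [default_config()], with overrides applied.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  if (length(user) == 0L) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}
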