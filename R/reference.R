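REFERENCE_FIXTURE_MD5 <- "af8709f87f2112ca78b1f772f9019e27"

#' Load the packaged reference condition tallies
#'
#' The nine-condition reference grid shipped with the package (three body
#' angles by three commanded displacements, detected and unusable counts with
#' and without the infrared channel, 100 breath episodes per condition). The
#' file is immutable: its checksum and structural invariants (row sums of 100
#' per mode) are verified on every load and any mismatch is a hard failure.
#'
#' @return Condition-tally data frame (see [run_protocol()] for the layout).
#' @export
#' @examples
#' ref <- load_reference_fixture()
#' pooled_table(ref)
load_reference_fixture <- function() {
  path <- system.file("extdata", "table2_reference.csv",
                      package = "apneasim", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, REFERENCE_FIXTURE_MD5)) {
    stop("reference fixture checksum mismatch: the packaged tally file has ",
         "been altered", call. = FALSE)
  }
  ref <- utils::read.csv(path)
  stopifnot(
    nrow(ref) == 9L,
    all(ref$detected_no_ir + ref$unusable_no_ir == 100L),
    all(ref$detected_ir + ref$unusable_ir == 100L),
    all(ref$detected_ir >= ref$detected_no_ir)
  )
  ref
}
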