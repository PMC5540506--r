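# Dataset-manifest bookkeeping for the Rfam-derived benchmark design:
# 13 ncRNA classes, a balanced training draw of 500 sequences per class
# (IRES is capped by availability at 320), an independent validation draw
# of 200 per class, and the 12-class subset (scaRNA removed) used when
# comparing against classifiers not trained on scaRNA.

.ncRnaClasses <- c("miRNA", "5S_rRNA", "5.8S_rRNA", "ribozyme", "CD-box",
                   "HACA-box", "scaRNA", "tRNA", "Intron_gpI",
                   "Intron_gpII", "IRES", "leader", "riboswitch")

#' Benchmark dataset manifests
#'
#' `trainingManifest()` lists the 13 ncRNA classes with the balanced
#' training counts (500 per class; IRES 320, all that are available after
#' redundancy reduction). `validationManifest()` lists the independent
#' validation draw (200 per class). `comparisonManifest()` drops scaRNA,
#' the class absent from the reference tool's training data.
#'
#' @return data.frame with columns `class` and `count`.
#' @examples
#' sum(trainingManifest()$count)    # 6320
#' sum(validationManifest()$count)  # 2600
#' sum(comparisonManifest()$count)  # 2400
#' @export
trainingManifest <- function() {
  data.frame(class = .ncRnaClasses,
             count = ifelse(.ncRnaClasses == "IRES", 320L, 500L))
}

#' @rdname trainingManifest
#' @export
validationManifest <- function() {
  data.frame(class = .ncRnaClasses, count = 200L)
}

#' @rdname trainingManifest
#' @export
comparisonManifest <- function() {
  m <- validationManifest()
  m[m$class != "scaRNA", , drop = FALSE]
}
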