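#' Adapter stubs for external design/evaluation tools
#'
#' The full-scale design-evaluation loop around this package depends on
#' external programs (an inverse-folding network, a folding predictor, a
#' structure-based function predictor, a structure clusterer, and a
#' co-folding predictor). Those executions are out of scope here; this
#' registry documents each tool's expected interface and provides a stub
#' whose invocation raises a clear not-installed error naming the tool
#' and its I/O, so pipelines can declare the dependency without silently
#' fabricating results.
#'
#' @return named list of adapters; each has `tool`, `purpose`, `inputs`,
#'   `outputs`, and a `run(...)` stub.
#' @export
external_adapters <- function() {
  mk <- function(tool, purpose, inputs, outputs) {
    force(tool); force(inputs); force(outputs)
    list(tool = tool, purpose = purpose, inputs = inputs, outputs = outputs,
         run = function(...) {
           stop(sprintf(paste0("external tool '%s' is not installed in this ",
                               "environment; expected inputs: %s; expected ",
                               "outputs: %s"),
                        tool, inputs, outputs), call. = FALSE)
         })
  }
  list(
    inverse_folding = mk(
      "ProteinMPNN",
      "design sequences for a generated backbone",
      "backbone PDB directory",
      "FASTA of designed sequences (one or more per backbone)"),
    folding = mk(
      "ESMFold",
      "refold designed sequences for self-consistency screening",
      "FASTA of sequences",
      "predicted-structure PDBs with per-residue pLDDT"),
    function_predictor = mk(
      "DeepFRI",
      "predict molecular-function term probabilities from structure",
      "PDB directory (run with the molecular-function ontology)",
      "per-structure term probability table (CSV)"),
    clusterer = mk(
      "FoldSeek",
      "cluster generated structures by structural similarity",
      "PDB directory (easy-cluster, TM-score threshold 0.5)",
      "cluster assignment table"),
    cofolding = mk(
      "Chai-1",
      "co-fold designed sequences with and without an effector ion",
      "FASTA plus optional ligand/ion specification",
      "predicted complex structures for bound/unbound screening")
  )
}
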