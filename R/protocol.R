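# End-to-end experiment protocol: class-split training, fine-tuning on the
# held-out classes, and final 2-way episodic testing -- in centralized or
# federated mode. This is the experiment grammar used by the command-line
# workflows and the synthetic benchmark.

#' Run a class-split experiment end to end
#'
#' Implements the two-stage protocol: train episodically on
#' `train_classes` (train split), validating on the same classes of the
#' valid split; fine-tune the best checkpoint on `test_classes` (their
#' train-split exams, validation 2-way 5-shot on the valid split); then
#' evaluate the best fine-tuned checkpoint with `eval_tasks` 2-way
#' `eval_k_shot`-shot episodes on the valid-split exams of `test_classes`.
#' In federated mode the two stages run under [run_federated()] with the
#' data split across clients.
#'
#' @param train_index,valid_index Full dataset indices (all classes).
#' @param train_classes,test_classes Disjoint class-id vectors.
#' @param backbone A backbone from [build_backbone()].
#' @param cfg A [train_config()] for the training stage; the fine-tuning
#'   stage reuses it with `val_k_shot = 5`.
#' @param mode `"central"` or `"federated"`.
#' @param fed A [fed_config()] (federated mode only; its `train`/`ft`
#'   slots are overridden by `cfg`).
#' @param eval_tasks,eval_k_shot,eval_n_query Final-test episode geometry
#'   (defaults 100 tasks, 2-way 8-shot).
#' @return List with the trained `checkpoint`, the fine-tuned
#'   `finetuned` checkpoint, the final `report` (a `metrics_report`) and,
#'   in federated mode, the `federated_report`.
#' @export
run_experiment <- function(train_index, valid_index, train_classes,
                           test_classes, backbone, cfg,
                           mode = c("central", "federated"),
                           fed = fed_config(train = cfg),
                           eval_tasks = 100L, eval_k_shot = 8L,
                           eval_n_query = NULL) {
  mode <- match.arg(mode)
  if (length(intersect(train_classes, test_classes)) > 0) {
    stop("train_classes and test_classes must be disjoint")
  }
  if (is.null(eval_n_query)) eval_n_query <- cfg$val_n_query
  tr <- suppressWarnings(subset_by_class(train_index, train_classes))
  tr_val <- suppressWarnings(subset_by_class(valid_index, train_classes))
  ft <- suppressWarnings(subset_by_class(train_index, test_classes))
  ft_val <- suppressWarnings(subset_by_class(valid_index, test_classes))
  test_idx <- ft_val

  ft_cfg <- cfg
  ft_cfg$val_k_shot <- 5L

  fed_report <- NULL
  if (mode == "central") {
    ck <- train_centralized(backbone, tr, tr_val, cfg)
    ck_ft <- finetune(ck, ft, ft_val, ft_cfg)
  } else {
    fed$train <- cfg
    fed$ft <- ft_cfg
    fed_report <- run_federated(backbone, tr, valid_index, ft, fed)
    ck <- NULL
    ck_ft <- fed_report$checkpoint
  }
  report <- evaluate_model(
    ck_ft, test_idx, n_tasks = eval_tasks, n_way = 2L,
    k_shot = eval_k_shot, n_query = eval_n_query,
    rng = rng_stream(derive_seed(cfg$seed, "eval")), cfg = cfg
  )
  list(checkpoint = ck, finetuned = ck_ft, report = report,
       federated_report = fed_report)
}
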