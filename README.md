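# cxrnet

Five-class chest radiograph abnormality classification — **No Finding,
Cardiomegaly, Effusion, Pneumothorax, Pneumonia** — as a fully testable
R pipeline, aimed at researchers who want to study and verify every
stage of such a system rather than treat it as a black box:

* a **synthetic radiograph phantom generator** that plants
  class-specific lesions (enlarged cardiac silhouette, basal effusion
  wedge with a fluid meniscus, apical pneumothorax crescent with a
  pleural line, clustered pneumonic patches) and records exact ground
  truth: lesion mask and bounding box, lung fields, diaphragm band;
* **three-channel preprocessing**: the z-score \(I_n = (I-\mu)/\sigma\),
  histogram equalisation + 5×5 Gaussian blur \(I_g\), and diaphragm
  removal \(I_d\) by the intensity threshold
  \(t = i_{min} + 0.9\,(i_{max}-i_{min})\) followed by morphological
  closing — stacked into the 224×224×3 model input;
* a **class-balancing augmentation planner**
  (\(plan_c = \max(0, n_{ref} - n_c)\), reference "No Finding") and a
  seeded transform chain (50% flips, ±15° rotation, ±5% translation,
  crop-and-resize; zoom and ±10% brightness/contrast for
  under-represented classes);
* three CNN **backbones** — ResNet-50-style bottleneck
  \(H(x) = F(x) + x\), ResNeXt-50 (32×4d grouped convolution), and an
  FSRF network whose blocks fuse multi-kernel branches (3×3 / 5×5,
  G = 32) through average–max channel and spatial attention gates with
  a softmax branch selection (reduction r = 16) — with a from-scratch
  training engine (compiled im2col/GEMM convolutions, batch
  normalisation, Adam with weight decay, early stopping, stratified
  splits and fivefold cross-validation);
* **Grad-CAM** saliency (\(\alpha_k\) = pooled logit gradients,
  \(ReLU(\sum_k \alpha_k A_k)\), bilinear upsampling, min-max
  normalisation) with overlay rendering and a localisation score
  against planted ground truth;
* **evaluation metrics** (confusion matrix, per-class and macro
  precision/recall/F1, one-vs-rest ROC/AUC) and **rule-based clinical
  report generation** from verbatim, editable per-label templates.

Every architectural block is verified against an independent naive
implementation and finite-difference gradients; the whole pipeline is
exercised end-to-end on the phantoms, where a scaled-down FSRF model
reaches ≥ 90% held-out accuracy within a few epochs and its saliency
maps concentrate on the planted lesions.

## Worked example

```r
library(cxrnet)

## class-balancing arithmetic for a published set of per-class counts
counts <- c("No Finding" = 5600, "Cardiomegaly" = 1668, "Effusion" = 4800,
            "Pneumothorax" = 3239, "Pneumonia" = 900)
planBalancing(counts)
```

```
AugmentationPlan (reference: No Finding = 5600 )
             original augment extended
No Finding       5600       0    FALSE
Cardiomegaly     1668    3932     TRUE
Effusion         4800     800    FALSE
Pneumothorax     3239    2361    FALSE
Pneumonia         900    4700     TRUE
```

Each class is topped up to the 5600 reference images (11,793 augmented
samples in total); classes under half the reference additionally get
the extended zoom/brightness transforms.

```r
## a phantom with ground truth, and its preprocessed stack
ph <- generatePhantom(phantomSpec("Effusion", imageSize = 64, seed = 3))
ph
st <- buildChannelStack(pixels(ph), size = 64, closingRadius = 3)
st
```

```
PhantomImage: Effusion (64 x 64)
  signature bbox: 31, 35, 42, 58
  diaphragm bbox: 51, 1, 64, 64
ChannelStack: 64 x 64 x 3 [normalized, equalized_blurred, diaphragm_removed_x1]
```

The bbox is the tight enclosure of the planted effusion (here in the
right lung); the diaphragm band occupies the bottom 22% of the image.

```r
## the reference architecture geometry
modelSummary(modelConfig("fsrfnet50"))
```

```
  stage  output                                   blocks n
1 conv1 112x112                         7x7,64, stride 2 1
2  pool   56x56                   3x3 max pool, stride 2 1
3 conv2   56x56   1x1,128 | FSRF M=2,G=32,r=16 | 1x1,256 3
4 conv3   28x28   1x1,256 | FSRF M=2,G=32,r=16 | 1x1,512 4
5 conv4   14x14  1x1,512 | FSRF M=2,G=32,r=16 | 1x1,1024 6
6 conv5     7x7 1x1,1024 | FSRF M=2,G=32,r=16 | 1x1,2048 3
7  head     1x1     global average pool, 5-d fc, softmax 1
```

A scaled-down training run (tiny FSRF backbone, 200 phantoms per class)
and the full evaluation/saliency/reporting chain are shown in the
methods vignette (`vignettes/cxrnet-methods.Rmd`); classification of a
single image goes through

```r
res <- classifyAndReport(model, "image.png", outJson = "report.json",
                         heatmapPath = "heatmap.png")
res$report$label        # "Effusion"
res$report$report_text  # the verbatim per-label clinical template
```

A thin command-line front end is available at `exec/cxrnet`
(`cxrnet simulate`, `preprocess`, `augment`, `train`, `evaluate`,
`explain`, `report`, `model-summary`).

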