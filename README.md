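# myodetect

Automatic localization of the left-ventricle (LV) myocardium region in
short-axis cardiac MR slices. Finding the LV region of interest — the
myocardial annulus together with the blood pool it encloses — is the usual
first step before cardiac registration, segmentation or volume measurement,
and it is hard for the usual reasons: the pool/wall contrast varies,
papillary muscles interfere, and the epicardial border fades into
surrounding tissue, particularly against low-signal lung.

`myodetect` implements a two-stage hybrid detector:

1. **Region proposal** by a structural-similarity-enhanced superpixel
   over-segmentation plus hierarchical merging. The SLIC distance is
   replaced by a hybrid similarity
   *S* = *S*<sub>pm</sub> · *S*<sub>im</sub> · *S*<sub>cm</sub> · *S*<sub>sm</sub> · *S*<sub>dm</sub>
   combining phase congruency (log-Gabor quadrature filters), intensity,
   contrast, structure and coordinate factors, each of the stabilized ratio
   form (2*ab* + *c*)/(*a*² + *b*² + *c*).
2. **Feature learning** by a stacked sparse autoencoder (SSAE): greedy
   layerwise pretraining under a KL sparsity penalty
   Σ<sub>j</sub> KL(ρ ‖ ρ̂<sub>j</sub>), then softmax-coupled fine-tuning
   with balanced batches.
3. **Classification** by a within-class neighborhood preserved C-SVC: kernel
   PCA of the centered Gaussian Gram matrix, a within-class *t*-NN graph
   whose scatter *S*<sub>w</sub> defines the transform
   *S* = *I* + η/(2*N*)·*S*<sub>w</sub>, and a standard soft-margin SVM in
   the *S*<sup>−1/2</sup>-transformed space (η = 0 recovers a plain
   Gaussian-kernel C-SVM).
4. **Refinement** by a multi-output ε-insensitive support vector regressor
   on the anchor/box codec
   *z* = ((*x*<sub>p</sub>−*x*<sub>a</sub>)/*w*<sub>a</sub>,
   (*y*<sub>p</sub>−*y*<sub>a</sub>)/*h*<sub>a</sub>,
   *w*<sub>p</sub>/*w*<sub>a</sub>, *h*<sub>p</sub>/*h*<sub>a</sub>), solved
   by IRWLS — plus hard-negative mining and non-maximum suppression.

A synthetic cardiac phantom generator (bright pool, myocardial annulus,
papillary spots, RV crescent, lung, bias field, Rician noise, per-subject
base-to-apex stacks) makes the whole pipeline trainable and testable with no
imaging data. See the methods vignette
(`vignettes/myodetect-methods.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(myodetect)

phantoms <- make_dataset(10, 3, seed = 7, split = c(train = 8, test = 2))
detector <- myo_detector(phantoms, myo_config(tau = 24), seed = 1)
detector
#> <myo_detector>
#>   trained on 24 slices, 6443 proposals (127 pos / 6105 neg)
#>   SSAE 576-400-300-200; classifier N=534 (+26 mined); regressor N=64

test <- dataset_slices(phantoms, tag = "test", mid_stack = TRUE)
detect_myocardium(detector, test[[1]])
#> <myo_detection> 1 box(es) from 262 proposals
#>   x_center y_center width height   prob
#> 1    86.24    66.19 33.94  31.53 0.9913

test[[1]]$gt
#> x_center y_center    width   height
#>     83.0     66.5     34.0     35.0

evaluate_detections(predict(detector, test), test)
#> <myo_eval>
#>   pixels: tp=2620 fp=412 fn=604 tn=79344
#>   Tpr=0.8127 Ppv=0.8641 F1=0.8376 AUC=NA
#>   DR(printed)=1.0000 DR(classical)=0.8324
#>   detection rate (IoU>0.5)=1.000, mean IoU=0.712 over 4 slices
```

The detector reports one box per slice (the single-object top-1 contract)
with its positive-class probability. Here the detected box on the first
held-out slice overlaps the ground-truth LV box at IoU ≈ 0.8; over the four
held-out mid-stack slices every detection clears IoU 0.5, and the pooled
pixelwise recall/precision of the reported boxes against the true boxes are
0.81/0.86. `Tpr`, `Ppv` and `F1` treat every pixel equally toward its
bounding box; `DR(printed)` is the overlap index 2|A∩B|/|A∪B| (twice the
IoU, clipped at 1) and `DR(classical)` the usual Dice coefficient. The
slice-level `AUC` is undefined (`NA`) when every slice is a hit.

Boxes use 0-based, half-open pixel coordinates
`(x_center, y_center, width, height)` throughout, so areas are exact pixel
counts.

A thin command-line front end ships in `inst/cli/myodetect` with verbs
`phantom`, `propose`, `train`, `detect` and `evaluate`.

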