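pt	scope
Acute kidney injury	aki_smq_narrow
Renal failure acute	aki_smq_narrow
Acute prerenal failure	aki_smq_narrow
Acute phosphate nephropathy	aki_smq_narrow
Anuria	aki_smq_narrow
Azotemia	aki_smq_narrow
Continuous hemodiafiltration	aki_smq_narrow
Dialysis	aki_smq_narrow
Fetal renal impairment	aki_smq_narrow
Hemodialysis	aki_smq_narrow
Hemofiltration	aki_smq_narrow
Neonatal anuria	aki_smq_narrow
Nephropathy toxic	aki_smq_narrow
Oliguria	aki_smq_narrow
Peritoneal dialysis	aki_smq_narrow
Prerenal failure	aki_smq_narrow
Renal failure	aki_smq_narrow
Renal failure neonatal	aki_smq_narrow
Renal impairment	aki_smq_narrow
Renal impairment neonatal	aki_smq_narrow
Subacute kidney injury	aki_smq_narrow
Artificial kidney device user	ckd_smq_narrow
Azotemia	ckd_smq_narrow
Renal failure chronic	ckd_smq_narrow
Chronic kidney disease	ckd_smq_narrow
Renal osteodystrophy	ckd_smq_narrow
Chronic kidney disease-mineral and bone disorder	ckd_smq_narrow
Coma uremic	ckd_smq_narrow
Diabetic end stage renal disease	ckd_smq_narrow
Dialysis	ckd_smq_narrow
Dialysis device insertion	ckd_smq_narrow
End stage renal disease	ckd_smq_narrow
Erythropoietin deficiency anemia	ckd_smq_narrow
Glomerulonephritis chronic	ckd_smq_narrow
Hemodialysis	ckd_smq_narrow
Hemofiltration	ckd_smq_narrow
Hepatorenal failure	ckd_smq_narrow
High turnover osteopathy	ckd_smq_narrow
Hyperparathyroidism secondary	ckd_smq_narrow
Kidney fibrosis	ckd_smq_narrow
Renal interstitial fibrosis	ckd_smq_narrow
Low turnover osteopathy	ckd_smq_narrow
Metabolic nephropathy	ckd_smq_narrow
Nephrogenic anemia	ckd_smq_narrow
Nephrogenic fibrosing dermopathy	ckd_smq_narrow
Nephrogenic systemic fibrosis	ckd_smq_narrow
Nephrosclerosis	ckd_smq_narrow
Oedema due to renal disease	ckd_smq_narrow
Pericarditis uremic	ckd_smq_narrow
Peritoneal dialysis	ckd_smq_narrow
Renal and liver transplant	ckd_smq_narrow
Renal and pancreas transplant	ckd_smq_narrow
Renal failure	ckd_smq_narrow
Renal replacement therapy	ckd_smq_narrow
Renal rickets	ckd_smq_narrow
Renal transplant	ckd_smq_narrow
Uremia odor	ckd_smq_narrow
Uremic acidosis	ckd_smq_narrow
Uremic encephalopathy	ckd_smq_narrow
Uremic gastropathy	ckd_smq_narrow
Uremic myopathy	ckd_smq_narrow
Uremic neuropathy	ckd_smq_narrow
Uremic pruritus	ckd_smq_narrow
Uridrosis	ckd_smq_narrow
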