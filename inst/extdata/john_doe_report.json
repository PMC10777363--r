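{
  "patient": {
    "name": "John Doe",
    "age": 54,
    "sex": "male",
    "bmi": 26.1,
    "diagnoses": ["ADHD", "depression"]
  },
  "prescriptions": [
    {
      "drug_name": "clomipramine",
      "drug_cas": "303-49-1",
      "brand_name": "Anafranil"
    },
    {
      "drug_name": "atomoxetine",
      "drug_cas": "83015-26-3",
      "brand_name": "Strattera"
    }
  ],
  "gene_variants": [
    { "gene": "CYP2D6", "diplotype": "*4/*6", "activity_score": 0 },
    { "gene": "CYP2C19", "diplotype": "*17/*17", "activity_score": 2.5 },
    { "gene": "CYP3A4", "diplotype": "*1A/*1B" }
  ],
  "guidelines": [
    {
      "gene": "CYP2D6",
      "diplotype": "*4/*6",
      "activity_score": 0,
      "metabolizer_status": "poor metabolizer",
      "drug_name": "clomipramine",
      "drug_cas": "303-49-1",
      "recommendation_text": "The risk of side effects is increased. Lower the dose to 70 percent of the standard dose and monitor the plasma concentrations of clomipramine and desmethylclomipramine.",
      "recommendation_category": "decrease dose",
      "severity": 3,
      "evidence_level": "1A",
      "source_url": "https://www.pharmgkb.org/guidelineAnnotation/PA166104959",
      "effect_text": "Increased metabolism of TCAs to less active compounds compared to NMs; Lower plasma concentrations of active drug will increase probability of pharmacotherapy failure",
      "source": "DPWG"
    },
    {
      "gene": "CYP2C19",
      "diplotype": "*17/*17",
      "activity_score": 2.5,
      "metabolizer_status": "ultrarapid metabolizer",
      "drug_name": "clomipramine",
      "drug_cas": "303-49-1",
      "recommendation_text": "Avoid tertiary amine tricyclic antidepressants. Consider an alternative drug not metabolized by CYP2C19.",
      "recommendation_category": "avoid",
      "severity": 2,
      "evidence_level": "1A",
      "source_url": "https://www.pharmgkb.org/guidelineAnnotation/PA166127556",
      "effect_text": "Increased metabolism of tertiary amines compared to NMs; decreased plasma concentrations of the parent drug relative to its metabolites",
      "source": "DPWG"
    },
    {
      "gene": "CYP2D6",
      "diplotype": "*4/*6",
      "activity_score": 0,
      "metabolizer_status": "poor metabolizer",
      "drug_name": "atomoxetine",
      "drug_cas": "83015-26-3",
      "recommendation_text": "Start with the standard dose and be alert to side effects; if needed, reduce the dose.",
      "recommendation_category": "decrease dose",
      "severity": 2,
      "evidence_level": "1A",
      "source_url": "https://www.pharmgkb.org/guidelineAnnotation/PA166181885",
      "effect_text": "Slower elimination of atomoxetine, higher plasma exposure compared to NMs",
      "source": "DPWG"
    }
  ]
}
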