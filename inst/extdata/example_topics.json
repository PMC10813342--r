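{
  "description": "Two example topics from an acute-appendicitis vs acute-cholecystitis differential, as top-word/probability lists for annotation display on the diagnostic plane.",
  "topics": {
    "abdominal-pain": {
      "Abdominal Pain": 0.25213, "Upper Abdomen": 0.15843, "Nausea": 0.03581,
      "Paroxysmal": 0.03412, "Anorexia": 0.03178, "Constipation": 0.02631,
      "CT Scan": 0.02123, "Effusion": 0.02015, "Swelling": 0.01561,
      "Digestive System": 0.01321, "Routine Blood Test": 0.01164,
      "Tenderness": 0.00975, "Bowel Sounds": 0.00716, "Pain Transfer": 0.00654,
      "Surgical Procedure": 0.00621, "Perforation": 0.00431, "Resection": 0.00411,
      "Medication Treatment": 0.00349, "Colic": 0.00184,
      "Traditional Chinese Medicine": 0.00094
    },
    "biliary-inflammation": {
      "Fever": 0.19834, "Chills": 0.18426, "Severe Pain": 0.17534,
      "Muscle Rigidity": 0.09642, "Shoulder Area": 0.09043, "Indigestion": 0.07642,
      "Belching": 0.07234, "Healing": 0.07049, "Shock": 0.04824,
      "Intestinal Obstruction": 0.04754, "Antibiotics": 0.04359,
      "Gallbladder": 0.02047, "Emergency": 0.02001,
      "Tenderness on Palpation": 0.01045, "Peritonitis": 0.01008,
      "Suppuration": 0.00843, "Cancer": 0.00724, "Greasiness": 0.00702,
      "Digestive System": 0.00497, "Pain": 0.00467
    }
  }
}
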