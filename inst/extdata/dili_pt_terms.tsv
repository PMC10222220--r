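# Reduced SYNTHETIC stand-in DILI preferred-term list, one MedDRA PT per
# line. Assembled from the hepatic SMQ families (drug-related hepatic
# disorders; cholestasis and jaundice of hepatic origin; liver-related
# investigations, signs and symptoms; hepatic failure, fibrosis, cirrhosis
# and other liver damage-related conditions; hepatitis, non-infectious).
# The full-scale definition comprises 228 PTs; drop a full SMQ export into
# this one-term-per-line format to use it.
Hepatic function abnormal
Liver disorder
Drug-induced liver injury
Hepatitis acute
Hepatitis fulminant
Hepatitis toxic
Hepatitis cholestatic
Hepatitis
Hepatocellular injury
Hepatotoxicity
Hepatic failure
Acute hepatic failure
Hepatic necrosis
Hepatic cirrhosis
Hepatic fibrosis
Hepatic steatosis
Cholestasis
Jaundice
Jaundice cholestatic
Ocular icterus
Hyperbilirubinaemia
Alanine aminotransferase increased
Aspartate aminotransferase increased
Blood bilirubin increased
Gamma-glutamyltransferase increased
Blood alkaline phosphatase increased
Hepatic enzyme increased
Liver function test abnormal
Transaminases increased
Hepatomegaly
Hepatic encephalopathy
Hepatorenal syndrome
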