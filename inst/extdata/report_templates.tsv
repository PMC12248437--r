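label	report
No Finding	The imaging examination of the chest revealed no abnormalities. The patient’s heart size and shape appear normal, and there is no evidence of fluid around the lungs or pleura (lining around the lungs and chest wall).
Cardiomegaly	Cardiomegaly is present. The heart appears enlarged on the X-ray. No pleural effusion, pneumonia, or pneumothorax were identified.
Effusion	The examination shows fluid accumulation in the space around the lungs (pleural effusion). Various factors, including infection, heart failure, or liver disease, could cause this. The patient’s heart size appears normal.
Pneumothorax	The imaging shows air present in the space between the chest wall and the lung (pneumothorax). This can cause sudden chest pain and shortness of breath. The patient’s heart size appears normal, and there is no significant pleural effusion.
Pneumonia	The examination reveals signs of infection within the lung tissue, consistent with pneumonia. This may present symptoms like cough, fever, and shortness of breath. The patient’s heart size and surrounding area appear normal.
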