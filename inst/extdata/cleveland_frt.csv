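feature,shap_xgboost,shap_rf,shap_svm
age,9,8,12
sex,5,9,5
cp,2,3,3
trestbps,12,12,11
chol,10,10,13
fbs,13,13,10
restecg,11,11,6
thalach,6,4,7
exang,8,6,4
oldpeak,7,5,9
slope,4,7,8
ca,1,2,2
thal,3,1,1
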