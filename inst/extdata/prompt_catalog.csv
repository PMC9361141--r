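"message_id","category","topic","slots","priority","condition","text"
"dia-entry-01","diary_feedback","diary","after_waking",5,"","Good morning! Please record last night's sleep in your diary."
"dia-entry-02","diary_feedback","diary","around_noon",3,"{""field"":""n_diary_entries"",""op"":""eq"",""value"":0}","Your sleep diary is still empty today - a quick entry keeps your plan on track."
"dia-se-low-01","diary_feedback","efficiency","evening",4,"{""field"":""last_se"",""op"":""lt"",""value"":85}","Last night's sleep efficiency was on the low side. Tonight, head to bed only when sleepy."
"dia-se-high-01","diary_feedback","efficiency","around_noon",4,"{""field"":""last_se"",""op"":""gt"",""value"":90}","Great sleep efficiency last night - your schedule is working well."
"dia-sol-01","diary_feedback","latency","evening",3,"{""field"":""last_sol"",""op"":""gt"",""value"":30}","Falling asleep took a while last night. A wind-down routine before bed can shorten it."
"dia-tst-01","diary_feedback","duration","around_noon",3,"{""field"":""last_tst"",""op"":""lt"",""value"":360}","You slept under six hours. Try to protect tonight's bed window."
"pra-streak-01","praise","adherence","around_noon;evening",6,"{""field"":""adherence_streak"",""op"":""ge"",""value"":3}","Three days of diary entries in a row - excellent consistency!"
"pra-streak-02","praise","adherence","after_waking",6,"{""field"":""adherence_streak"",""op"":""ge"",""value"":7}","A full week of diary entries. Your record is a real asset to your sleep plan."
"pra-se-01","praise","efficiency","after_waking",5,"{""all"":[{""field"":""last_se"",""op"":""ge"",""value"":90},{""field"":""adherence_streak"",""op"":""ge"",""value"":3}]}","Sleep efficiency above 90% and a steady diary habit - keep it up!"
"hyg-light-01","hygiene","light","after_waking",2,"","Open the curtains soon after waking - morning light anchors your body clock."
"hyg-light-02","hygiene","light","before_bedtime",2,"","Dim the lights and put screens away in the hour before bed."
"hyg-rhythm-01","hygiene","rhythm","after_waking",2,"","Getting up at the same time every day, even on holidays, steadies your rhythm."
"hyg-caffeine-01","hygiene","caffeine","evening",3,"{""field"":""caffeine"",""op"":""is_true""}","Caffeine lingers for hours - make this your last coffee or tea of the day."
"hyg-caffeine-02","hygiene","caffeine","around_noon",2,"{""field"":""caffeine"",""op"":""is_true""}","Enjoy coffee before mid-afternoon; later cups can fragment tonight's sleep."
"hyg-alcohol-01","hygiene","alcohol","evening",3,"{""field"":""alcohol"",""op"":""is_true""}","A nightcap may bring sleep faster but breaks it up later. Lighter evenings sleep better."
"hyg-smoking-01","hygiene","smoking","before_bedtime",3,"{""field"":""smoking"",""op"":""is_true""}","Nicotine is a stimulant - avoid smoking in the hour before bed."
"hyg-exercise-01","hygiene","exercise","around_noon",2,"","A brisk walk today helps you sleep tonight - just keep hard exercise out of the late evening."
"hyg-nap-01","hygiene","napping","around_noon",3,"{""field"":""last_nap"",""op"":""gt"",""value"":30}","Long naps eat into night sleep. If you nap, keep it under 30 minutes and before 3 pm."
"hyg-bath-01","hygiene","bathing","evening",2,"","A warm bath 1-2 hours before bed helps your body cool down into sleep."
"hyg-meal-01","hygiene","diet","evening",2,"","Finish dinner at least two hours before bedtime; a heavy late meal disturbs sleep."
"hyg-temp-01","hygiene","temperature","before_bedtime",1,"","A cool, dark, quiet bedroom is the easiest sleep aid there is."
"hyg-stress-01","hygiene","emotional_distress","evening",2,"","Worries keeping you up? Jot them down before bed and set them aside for tomorrow."
"hyg-sound-01","hygiene","sound","before_bedtime",1,"","Silence your phone notifications overnight - uninterrupted nights build better sleep."
"hyg-hypnotic-01","hygiene","hypnotics","evening",2,"{""field"":""hypnotic_use"",""op"":""is_true""}","If you use sleep medication, take it as prescribed and discuss changes with your doctor."
"stc-sleepy-01","stimulus_control","bed_association","before_bedtime",4,"","Go to bed only when you actually feel sleepy, not just tired."
"stc-leave-01","stimulus_control","bed_association","before_bedtime",3,"","Awake in bed for what feels like 20 minutes? Get up, relax elsewhere, return when sleepy."
"stc-bedonly-01","stimulus_control","bed_association","evening",3,"","Use your bed only for sleep - reading, eating, and scrolling belong elsewhere."
"stc-wake-01","stimulus_control","wake_time","after_waking",3,"","Keep your set wake time whatever last night looked like - it is the anchor of the program."
"stc-clock-01","stimulus_control","bed_association","before_bedtime",2,"","Turn the clock face away - watching the minutes pass feeds wakefulness."
"stc-sol-01","stimulus_control","bed_association","evening",4,"{""field"":""last_sol"",""op"":""gt"",""value"":30}","Long time to fall asleep last night? Delay bedtime until real sleepiness arrives."
"res-window-01","restriction","schedule","before_bedtime",5,"","Your bed window starts soon - hold off on bed until your set bedtime."
"res-wake-01","restriction","schedule","after_waking",5,"","Time to get up and out of bed - lingering dilutes your sleep efficiency."
"res-se-high-01","restriction","titration","evening",4,"{""field"":""last_se"",""op"":""gt"",""value"":90}","Efficiency above 90% - if the whole week holds, your bed window earns 15 extra minutes."
"res-se-mid-01","restriction","titration","evening",3,"{""all"":[{""field"":""last_se"",""op"":""ge"",""value"":85},{""field"":""last_se"",""op"":""le"",""value"":90}]}","Solid efficiency. Keeping the same bed window this week consolidates your sleep."
"res-se-low-01","restriction","titration","evening",4,"{""field"":""last_se"",""op"":""lt"",""value"":85}","Efficiency under 85% - a slightly shorter bed window will deepen your sleep."
"res-consist-01","restriction","schedule","around_noon",2,"","Matching your diary times to your set schedule is what makes the titration work."
"res-sleepy-01","restriction","daytime","around_noon",3,"{""field"":""last_tst"",""op"":""lt"",""value"":330}","Restricted nights can bring daytime sleepiness at first - be careful driving, and hold the plan."
"res-isi-01","restriction","progress","evening",2,"{""field"":""current_isi"",""op"":""ge"",""value"":8}","Insomnia symptoms take a few weeks to respond - the schedule is doing the slow work."
"res-isi-02","restriction","progress","around_noon",2,"{""field"":""current_isi"",""op"":""lt"",""value"":8}","Your insomnia score is in the healthy range - the schedule is paying off."
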